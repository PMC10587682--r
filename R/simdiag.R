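#' Simulate replicate datasets under a population model
#'
#' Holds the design fixed (doses, sampling times, covariates) and redraws
#' the between-subject etas per subject and the residual errors per
#' observation for each of `k` replicates — the ensemble underlying NPDE
#' and prediction-corrected VPC diagnostics.
#'
#' @param ds A `pk_dataset`.
#' @param model Model id or `vpa_model`.
#' @param k Number of replicates (2000 for production diagnostics; smaller
#'   values are fine for calibration studies).
#' @param seed Integer seed, or `NULL`.
#' @return A `sim_ensemble`: list with `sims` (k x n_obs matrix, mg/L),
#'   `pred` (population predictions), `meta` (per-observation id/time/tad
#'   and the observed DV), `k`, `seed`, `model`.
#' @export
simulate_replicates <- function(ds, model, k = 2000L, seed = NULL) {
  spec <- model_spec(model)
  if (k < 1) abort("`k` must be >= 1.", class = "vpaeval_domain_error")
  design <- obs_design(ds)
  cov <- subject_covariates(ds)
  cov <- cov[match(design$ids, cov$id), ]
  typ <- typical_parameters(spec, cov)
  n_obs <- nrow(design$obs)
  n_subj <- length(design$ids)
  cov_obs <- cov[design$obs$subj, ]

  pred <- spec$observation(
    pred_structural(design, expand_pars(typ, design), spec$structural),
    cov_obs)

  sims <- with_seed_maybe(seed, {
    p <- length(spec$eta)
    eta_all <- if (all(spec$omega == 0)) {
      matrix(0, k * n_subj, p)
    } else {
      MASS::mvrnorm(k * n_subj, mu = rep(0, p), Sigma = spec$omega)
    }
    if (p == 1L) eta_all <- matrix(eta_all, ncol = 1)
    colnames(eta_all) <- spec$eta
    # long layout: replicate index varies slowest
    rep_idx <- rep(seq_len(k), each = n_obs)
    subj_long <- rep(design$obs$subj, k)
    pars_long <- expand_pars(typ, design)[rep(seq_len(n_obs), k), ,
                                          drop = FALSE]
    for (nm in spec$eta) {
      e <- eta_all[(rep_idx - 1L) * n_subj + subj_long, nm]
      pars_long[[nm]] <- pars_long[[nm]] * exp(e)
    }
    long_design <- list(
      obs = design$obs[rep(seq_len(n_obs), k), ],
      singles = NULL, ids = design$ids)
    if (!is.null(design$singles)) {
      s <- design$singles
      long_design$singles <- tibble::tibble(
        obs = rep(s$obs, k) + rep((seq_len(k) - 1L) * n_obs,
                                  each = nrow(s)),
        amt = rep(s$amt, k), dt = rep(s$dt, k))
    }
    conc <- pred_structural(long_design, pars_long, spec$structural)
    conc <- spec$observation(conc, cov_obs[rep(seq_len(n_obs), k), ])
    eps <- rnorm(length(conc))
    conc <- if (spec$residual$type == "additive") {
      conc + spec$residual$value * eps
    } else {
      conc * (1 + spec$residual$value * eps)
    }
    matrix(conc, nrow = k, ncol = n_obs, byrow = TRUE)
  })

  structure(list(sims = sims, pred = pred,
                 meta = design$obs[c("id", "subj", "time", "tad", "dv")],
                 k = k, seed = seed, model = spec$id),
            class = "sim_ensemble")
}

#' Normalized prediction distribution errors
#'
#' Per subject, the observed vector and each simulated replicate are
#' decorrelated with the lower-triangular Cholesky factor of the empirical
#' simulated covariance (centered at the empirical simulated mean); the
#' prediction discrepancy `pde` of each observation is the fraction of
#' decorrelated simulations below the decorrelated observation, clamped to
#' `[1/(2k), 1 - 1/(2k)]`, and `npde = qnorm(pde)`. Under the
#' data-generating model the npde are standard normal.
#'
#' @param ensemble A `sim_ensemble` from [simulate_replicates()].
#' @param obs Optional observation vector aligned with the ensemble columns;
#'   defaults to the DV stored in the ensemble.
#' @return An `npde_result`: tibble `id`, `time`, `tad`, `obs`, `pde`,
#'   `npde`; test p-values are added by [npde_tests()].
#' @export
compute_npde <- function(ensemble, obs = NULL) {
  meta <- ensemble$meta
  y <- obs %||% meta$dv
  if (anyNA(y)) abort("Observations required to compute npde.",
                      class = "vpaeval_domain_error")
  k <- ensemble$k
  npde <- pde <- numeric(nrow(meta))
  for (s in unique(meta$subj)) {
    ix <- which(meta$subj == s)
    S <- ensemble$sims[, ix, drop = FALSE]
    mu <- colMeans(S)
    V <- cov(S)
    L <- tryCatch(t(chol(V)), error = function(e) {
      warn("Singular empirical covariance; ridge-regularized.")
      t(chol(V + diag(1e-8 * max(diag(V), 1), nrow(V))))
    })
    ystar <- forwardsolve(L, y[ix] - mu)
    sstar <- forwardsolve(L, t(S) - mu)   # n_i x k
    for (j in seq_along(ix)) {
      frac <- mean(sstar[j, ] < ystar[j])
      pde[ix[j]] <- min(max(frac, 1 / (2 * k)), 1 - 1 / (2 * k))
    }
  }
  npde <- qnorm(pde)
  out <- dplyr::bind_cols(meta[c("id", "time", "tad")],
                          tibble::tibble(obs = y, pde = pde, npde = npde))
  class(out) <- c("npde_result", class(tibble::tibble()))
  out
}

#' Three-test battery on npde values
#'
#' Tests the standard-normal null: Wilcoxon signed-rank test of zero mean,
#' a two-sided chi-square test of unit variance (the construction used for
#' the exact variance test in reference npde software), and the
#' Shapiro-Wilk normality test. The global decision is Bonferroni over the
#' three tests: reject when `min(p) < alpha/3`, with the adjusted global p
#' reported as `min(1, 3 min(p))`.
#'
#' @param r An `npde_result` with at least 10 values.
#' @param alpha Global significance level (default 0.05).
#' @return The input with attributes `p_mean`, `p_var`, `p_norm`,
#'   `p_global`, `reject_global`, `alpha` set; retrieve them as a one-row
#'   tibble with [glance()][generics::glance].
#' @export
npde_tests <- function(r, alpha = 0.05) {
  x <- r$npde
  if (length(x) < 10) abort("Need at least 10 npde values.",
                            class = "vpaeval_domain_error")
  p_mean <- wilcox.test(x, mu = 0, exact = FALSE)$p.value
  n <- length(x)
  stat <- (n - 1) * var(x)
  p_var <- min(1, 2 * min(pchisq(stat, n - 1),
                          1 - pchisq(stat, n - 1)))
  p_norm <- shapiro.test(if (n > 4999) sample(x, 4999) else x)$p.value
  p_min <- min(p_mean, p_var, p_norm)
  attr(r, "p_mean") <- p_mean
  attr(r, "p_var") <- p_var
  attr(r, "p_norm") <- p_norm
  attr(r, "p_global") <- min(1, 3 * p_min)
  attr(r, "reject_global") <- p_min < alpha / 3
  attr(r, "alpha") <- alpha
  r
}

#' Prediction-corrected visual predictive check table
#'
#' Observations and simulations are normalized by the ratio of the bin
#' median population prediction to each record's own prediction
#' (`pcY = Y * median(PRED in bin) / PRED`), binned on time after dose with
#' quantile-based automatic binning; per bin the observed 2.5th/50th/97.5th
#' percentiles are compared with the simulated confidence band of each
#' percentile across the `k` replicates.
#'
#' @param ensemble A `sim_ensemble`.
#' @param obs Optional observation vector; defaults to the stored DV.
#' @param n_bins Number of automatic bins on time after dose (empty or
#'   duplicate-edge bins are merged).
#' @param ci Width of the simulated confidence band (default 0.95).
#' @return A `pcvpc_result` tibble: one row per bin x percentile with the
#'   observed percentile of prediction-corrected observations and the
#'   simulated band (`sim_lo`, `sim_mid`, `sim_hi`).
#' @export
pcvpc <- function(ensemble, obs = NULL, n_bins = 4L, ci = 0.95) {
  if (n_bins < 1) abort("`n_bins` must be >= 1.",
                        class = "vpaeval_domain_error")
  meta <- ensemble$meta
  y <- obs %||% meta$dv
  if (anyNA(y)) abort("Observations required for a pcVPC.",
                      class = "vpaeval_domain_error")
  tad <- meta$tad
  edges <- unique(quantile(tad, probs = seq(0, 1, length.out = n_bins + 1),
                           names = FALSE))
  if (length(edges) < 2) edges <- c(edges, edges + 1e-9)
  bin <- cut(tad, breaks = edges, include.lowest = TRUE)
  if (nlevels(bin) < n_bins) {
    inform(sprintf("Automatic binning produced %d bin(s) for %d requested (ties on time after dose merged).",
                   nlevels(bin), n_bins))
  }
  probs <- c(0.025, 0.5, 0.975)
  qlo <- (1 - ci) / 2
  rows <- list()
  for (b in levels(bin)) {
    ix <- which(bin == b)
    med_pred <- median(ensemble$pred[ix])
    corr <- med_pred / ensemble$pred[ix]
    pc_obs <- y[ix] * corr
    pc_sims <- sweep(ensemble$sims[, ix, drop = FALSE], 2, corr, `*`)
    obs_q <- quantile(pc_obs, probs, names = FALSE)
    sim_q <- apply(pc_sims, 1, quantile, probs = probs, names = FALSE)
    if (is.null(dim(sim_q))) sim_q <- matrix(sim_q, nrow = length(probs))
    band <- apply(sim_q, 1, quantile,
                  probs = c(qlo, 0.5, 1 - qlo), names = FALSE)
    b_pos <- match(b, levels(bin))
    rows[[b]] <- tibble::tibble(
      bin = b,
      t_lo = edges[b_pos],
      t_hi = edges[b_pos + 1],
      n = length(ix),
      percentile = 100 * probs,
      observed = obs_q,
      sim_lo = band[1, ], sim_mid = band[2, ], sim_hi = band[3, ]
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pcvpc_result", class(tibble::tibble()))
  out
}
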