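#' Maximum a posteriori estimation of individual random effects
#'
#' For each subject, finds the eta vector minimizing
#' `sum_j ((obs_j - ipred_j(eta))^2 / sigma_j^2 + log sigma_j^2)
#'  + eta' Omega^-1 eta`,
#' where `sigma_j` follows the model's residual form (proportional sigma
#' evaluated at IPRED, the standard MAP convention). One-dimensional eta
#' supports use golden-section search; higher dimensions use quasi-Newton
#' from `eta = 0`.
#'
#' @param ds A `pk_dataset`.
#' @param model Model id or `vpa_model`.
#' @param use_obs Which observations inform the fit: `"all"`, `"first"`
#'   (the earliest per subject), or an integer k for the first k per
#'   subject.
#' @param omega_scale Optional multiplier on the model's omega matrix
#'   (e.g. a value near 0 forces complete shrinkage to the population).
#' @return Tibble, one row per subject: `id`, one `eta_<par>` column per
#'   random effect, `objective`, `converged`, `n_obs_used`. Per-eta
#'   shrinkage (`1 - SD(eta_hat)/omega`) is attached as attribute
#'   `"shrinkage"`.
#' @export
map_estimate <- function(ds, model, use_obs = "all", omega_scale = 1) {
  spec <- model_spec(model)
  design <- obs_design(ds)
  cov <- subject_covariates(ds)
  cov <- cov[match(design$ids, cov$id), ]
  typ <- typical_parameters(spec, cov)
  omega <- spec$omega * omega_scale
  oinv <- solve(omega + diag(1e-12, nrow(omega)))
  p <- length(spec$eta)

  keep <- .select_obs(design$obs, use_obs)
  rows <- purrr::map(seq_along(design$ids), function(s) {
    d_s <- design$obs[design$obs$subj == s & keep, ]
    if (!nrow(d_s) || anyNA(d_s$dv)) {
      return(tibble::tibble(id = design$ids[s], objective = NA_real_,
                            converged = FALSE, n_obs_used = 0L))
    }
    sub_design <- list(obs = d_s, singles = .subset_singles(design, d_s),
                       ids = design$ids)
    fn <- function(eta) {
      pars <- typ[s, , drop = FALSE]
      for (j in seq_len(p)) pars[[spec$eta[j]]] <-
          pars[[spec$eta[j]]] * exp(eta[j])
      pars <- pars[rep(1, nrow(d_s)), , drop = FALSE]
      f <- pred_structural(sub_design, pars, spec$structural)
      f <- spec$observation(f, cov[rep(s, nrow(d_s)), ])
      sig <- if (spec$residual$type == "additive") {
        rep(spec$residual$value, length(f))
      } else {
        spec$residual$value * pmax(f, 1e-8)
      }
      sum((d_s$dv - f)^2 / sig^2 + log(sig^2)) +
        as.numeric(t(eta) %*% oinv %*% eta)
    }
    if (p == 1L) {
      opt <- optimize(function(e) fn(e), interval = c(-15, 15),
                      tol = 1e-10)
      eta_hat <- opt$minimum
      obj <- opt$objective
      conv <- TRUE
    } else {
      opt <- optim(rep(0, p), fn, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12))
      eta_hat <- opt$par
      obj <- opt$value
      conv <- opt$convergence == 0
    }
    # the MAP objective can never exceed its value at eta = 0
    if (obj > fn(rep(0, p))) {
      eta_hat <- rep(0, p)
      obj <- fn(rep(0, p))
    }
    out <- tibble::tibble(id = design$ids[s])
    for (j in seq_len(p)) out[[paste0("eta_", spec$eta[j])]] <- eta_hat[j]
    out$objective <- obj
    out$converged <- conv
    out$n_obs_used <- nrow(d_s)
    out
  })
  res <- dplyr::bind_rows(rows)
  om_sd <- sqrt(diag(omega))
  shr <- vapply(seq_len(p), function(j) {
    e <- res[[paste0("eta_", spec$eta[j])]]
    1 - sd(e, na.rm = TRUE) / om_sd[j]
  }, numeric(1))
  attr(res, "shrinkage") <- setNames(shr, spec$eta)
  res
}

.select_obs <- function(obs, use_obs) {
  if (identical(use_obs, "all")) return(rep(TRUE, nrow(obs)))
  k <- if (identical(use_obs, "first")) 1L else as.integer(use_obs)
  rk <- stats::ave(obs$time, obs$subj,
                   FUN = function(t) rank(t, ties.method = "first"))
  rk <= k
}

.subset_singles <- function(design, d_s) {
  if (is.null(design$singles)) return(NULL)
  s <- design$singles[design$singles$obs %in% d_s$obs, ]
  if (!nrow(s)) return(NULL)
  s$obs <- match(s$obs, d_s$obs)
  s
}

#' Bayesian forecast of the last observation from one prior observation
#'
#' The forecasting protocol for therapeutic drug monitoring: per subject
#' with at least two observations, the random effects are MAP-estimated from
#' the earliest observation alone, the individual prediction (IPRED) is
#' computed at the last observation's time, and the individual prediction
#' error `IPE% = (IPRED - OBS)/OBS * 100` is recorded. Subjects with fewer
#' than two observations are skipped (counted in attribute
#' `"n_skipped"`).
#'
#' @param ds A `pk_dataset`.
#' @param model Model id or `vpa_model`.
#' @param n_priors Number of earliest observations used as priors
#'   (default 1; the protocol's headline case).
#' @return Tibble of forecast records: `id`, `prior_obs_used`,
#'   `target_time`, `ipred`, `obs`, `ipe`.
#' @export
forecast_last_obs <- function(ds, model, n_priors = 1L) {
  spec <- model_spec(model)
  obs_count <- table(ds$id[ds$evid == 0])
  eligible <- names(obs_count)[obs_count >= 2]
  skipped <- setdiff(names(obs_count), eligible)
  if (length(skipped)) {
    inform(sprintf("Skipped %d subject(s) with fewer than 2 observations.",
                   length(skipped)))
  }
  ds_e <- ds[ds$id %in% eligible, ]
  class(ds_e) <- class(ds)
  est <- map_estimate(ds_e, spec, use_obs = n_priors)
  eta <- as.matrix(est[paste0("eta_", spec$eta)])
  colnames(eta) <- spec$eta
  ip <- individual_predictions(ds_e, spec, eta)
  last <- ip |>
    dplyr::group_by(.data$id) |>
    dplyr::slice_max(.data$time, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  out <- tibble::tibble(
    id = last$id,
    prior_obs_used = est$n_obs_used[match(last$id, est$id)],
    target_time = last$time,
    ipred = last$ipred,
    obs = last$obs,
    ipe = prediction_errors(last$ipred, last$obs)
  )
  attr(out, "n_skipped") <- length(skipped)
  attr(out, "shrinkage") <- attr(est, "shrinkage")
  out
}

#' Summarize individual prediction errors from forecasting
#'
#' Applies the MDPE/MAPE/F20/F30 summarization to IPE values, yielding
#' MDIPE, MAIPE, IF20, IF30.
#'
#' @param records Output of [forecast_last_obs()] (or any data frame with
#'   an `ipe` column).
#' @return A `pe_summary` of the IPE values.
#' @export
forecast_metrics <- function(records) {
  summarize_pe(records$ipe)
}
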