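# Per-observation dosing design extracted once from a pk_dataset.
# Each observation is linked to the most recent steady-state dose row at or
# before it (amount, interval, offset) plus any later single doses, which
# are added by superposition.
obs_design <- function(ds) {
  obs_idx <- which(ds$evid == 0)
  ids <- unique(ds$id)
  subj_of <- match(ds$id, ids)
  rows <- vector("list", length(obs_idx))
  singles <- list()
  for (k in seq_along(obs_idx)) {
    i <- obs_idx[k]
    sub_rows <- which(ds$id == ds$id[i] & ds$evid == 1 & ds$time <= ds$time[i])
    sub <- ds[sub_rows, ]
    ss <- sub[sub$ss == 1, ]
    if (nrow(ss)) {
      last_ss <- ss[which.max(ss$time), ]
      amt <- last_ss$amt; tau <- last_ss$ii
      toff <- ds$time[i] - last_ss$time
      post <- sub[sub$ss == 0 & sub$time >= last_ss$time, ]
    } else {
      amt <- NA_real_; tau <- NA_real_; toff <- NA_real_
      post <- sub[sub$ss == 0, ]
    }
    rows[[k]] <- tibble::tibble(
      obs = k, row = i, id = ds$id[i], subj = subj_of[i],
      time = ds$time[i], tad = ds$tad[i], dv = ds$dv[i],
      amt = amt, tau = tau, toff = toff
    )
    if (nrow(post)) {
      singles[[length(singles) + 1L]] <- tibble::tibble(
        obs = k, amt = post$amt, dt = ds$time[i] - post$time)
    }
  }
  list(obs = dplyr::bind_rows(rows),
       singles = if (length(singles)) dplyr::bind_rows(singles) else NULL,
       ids = ids)
}

# Structural concentration for per-observation parameter vectors.
# `pars` columns are aligned with design$obs rows (recycled if length 1).
pred_structural <- function(design, pars, structural = "1cmt") {
  d <- design$obs
  has_ss <- !is.na(d$amt)
  conc <- numeric(nrow(d))
  if (any(has_ss)) {
    conc[has_ss] <- if (structural == "2cmt") {
      with(pars, conc_2cmt_ss(cl[has_ss], vc[has_ss], vp[has_ss], q[has_ss],
                              ka[has_ss], d$amt[has_ss], d$tau[has_ss],
                              d$toff[has_ss], tlag[has_ss]))
    } else {
      with(pars, conc_1cmt_ss(cl[has_ss], v[has_ss], ka[has_ss],
                              d$amt[has_ss], d$tau[has_ss], d$toff[has_ss],
                              tlag[has_ss]))
    }
  }
  if (!is.null(design$singles)) {
    s <- design$singles
    for (j in seq_len(nrow(s))) {
      k <- s$obs[j]
      conc[k] <- conc[k] + if (structural == "2cmt") {
        conc_2cmt_single(pars$cl[k], pars$vc[k], pars$vp[k], pars$q[k],
                         pars$ka[k], s$amt[j], s$dt[j], pars$tlag[k])
      } else {
        conc_1cmt_single(pars$cl[k], pars$v[k], pars$ka[k], s$amt[j],
                         s$dt[j], pars$tlag[k])
      }
    }
  }
  conc
}

# Expand per-subject parameter tibble to per-observation rows
expand_pars <- function(pars_by_subject, design) {
  pars_by_subject[design$obs$subj, , drop = FALSE]
}

#' Population predictions (PRED) for every observation
#'
#' Concentration predictions with all random effects at zero, one value per
#' observation event. For models whose structural compartment tracks unbound
#' drug, the binding observation function is applied so PRED is on the
#' observed (total-concentration) scale. PRED never depends on the observed
#' DV values.
#'
#' @param ds A `pk_dataset`.
#' @param model Model id or `vpa_model`.
#' @return Tibble: `id`, `time`, `tad`, `obs` (the DV, `NA` if missing),
#'   `pred` (mg/L).
#' @export
population_predictions <- function(ds, model) {
  spec <- model_spec(model)
  design <- obs_design(ds)
  cov <- subject_covariates(ds)
  cov <- cov[match(design$ids, cov$id), ]
  typ <- typical_parameters(spec, cov)
  pars <- expand_pars(typ, design)
  conc <- pred_structural(design, pars, spec$structural)
  cov_obs <- cov[design$obs$subj, ]
  pred <- spec$observation(conc, cov_obs)
  tibble::tibble(id = design$obs$id, time = design$obs$time,
                 tad = design$obs$tad, obs = design$obs$dv, pred = pred)
}

#' Individual predictions (IPRED) for given random-effect values
#'
#' Concentration predictions with the random effects set to supplied values
#' — e.g. MAP estimates from [map_estimate()] or stored simulation truths.
#'
#' @param ds A `pk_dataset`.
#' @param model Model id or `vpa_model`.
#' @param eta Numeric matrix, one row per subject (in `unique(ds$id)`
#'   order), columns named after the model's eta parameters.
#' @return Tibble: `id`, `time`, `tad`, `obs`, `ipred`.
#' @export
individual_predictions <- function(ds, model, eta) {
  spec <- model_spec(model)
  design <- obs_design(ds)
  cov <- subject_covariates(ds)
  cov <- cov[match(design$ids, cov$id), ]
  typ <- typical_parameters(spec, cov)
  for (nm in spec$eta) typ[[nm]] <- typ[[nm]] * exp(eta[, nm])
  pars <- expand_pars(typ, design)
  conc <- pred_structural(design, pars, spec$structural)
  cov_obs <- cov[design$obs$subj, ]
  tibble::tibble(id = design$obs$id, time = design$obs$time,
                 tad = design$obs$tad, obs = design$obs$dv,
                 ipred = spec$observation(conc, cov_obs))
}
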