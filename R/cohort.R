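#' Configuration of a virtual pediatric TDM cohort
#'
#' Defaults emulate a routine pediatric valproate monitoring population:
#' age lognormal with median 4.92 years truncated to 0.17-15 years; weight
#' linked to age through a coarse growth rule (`2 * age + 9` kg with 15%
#' lognormal noise) truncated to 4-70 kg; daily dose lognormal with median
#' 23.44 mg/kg/day truncated to 8.7-57.69, rounded to 10-mg total-dose
#' strengths and split into 1-3 administrations per day; formulation mix
#' 76% syrup / 24% sustained release; albumin normal(42.21, 3.65) g/L;
#' carbamazepine and lamotrigine co-medication at the observed per-sample
#' prevalences (3/255 and 10/255), other co-medication (levetiracetam,
#' oxcarbazepine, topiramate, clonazepam) pooled into one flag; 69% male;
#' 26% of subjects contribute a second trough; assay lower limit of
#' quantification 1 mg/L.
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer seed driving all draws.
#' @param truth_model Model id or `vpa_model` used as simulation truth by
#'   [simulate_cohort()].
#' @param samples_per_subject `1`, `2`, or `NULL` for the mixed design
#'   (second sample with probability `p_second_sample`).
#' @param ... Overrides for any default listed in the description (see the
#'   returned list for names).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 202L, seed = 1L,
                          truth_model = "serrano2019",
                          samples_per_subject = NULL, ...) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    seed = as.integer(seed),
    truth_model = truth_model,
    samples_per_subject = samples_per_subject,
    age_median = 4.92, age_sdlog = 0.555, age_range = c(0.17, 15.0),
    weight_slope = 2.0, weight_intercept = 9.0, weight_cv = 0.15,
    weight_range = c(4.0, 70.0),
    ddw_median = 23.44, ddw_sdlog = 0.31, ddw_range = c(8.70, 57.69),
    dose_rounding = 10,
    formulation_probs = c(syrup = 194 / 255, sustained_release = 61 / 255),
    times_per_day_probs = c(`1` = 0.15, `2` = 0.70, `3` = 0.15),
    albumin_mean = 42.21, albumin_sd = 3.65, albumin_range = c(29.7, 70.5),
    p_male = 139 / 202,
    p_cbz = 3 / 255, p_ltg = 10 / 255, p_pb = 0, p_pht = 0, p_clb = 0,
    p_other_comed = 82 / 255,
    p_uncontrolled = 0.3,
    p_second_sample = 53 / 202,
    loq = 1
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) {
    abort(sprintf("Unknown cohort_config field(s): %s",
                  paste(bad, collapse = ", ")),
          class = "vpaeval_config_error")
  }
  cfg <- modifyList(cfg, over)
  structure(cfg, class = "cohort_config")
}

# Truncated sampling by rejection; `draw` receives the indices to redraw so
# subject-linked location parameters stay attached to their subjects
rtrunc <- function(n, draw, range) {
  out <- draw(seq_len(n))
  bad <- which(out < range[1] | out > range[2])
  tries <- 0
  while (length(bad) && tries < 1000) {
    out[bad] <- draw(bad)
    bad <- bad[out[bad] < range[1] | out[bad] > range[2]]
    tries <- tries + 1
  }
  pmin(pmax(out, range[1]), range[2])
}

#' Generate subject covariates for a virtual cohort
#'
#' @param cfg A [cohort_config()].
#' @return Tibble of covariates, one row per subject, including the derived
#'   `daily_dose_per_kg` (exact ratio of the rounded daily dose to weight)
#'   and `pma`.
#' @export
generate_covariates <- function(cfg = cohort_config()) {
  with_seed_maybe(cfg$seed, {
    n <- cfg$n_subjects
    age <- rtrunc(n, function(ix) stats::rlnorm(length(ix),
                                                log(cfg$age_median),
                                                cfg$age_sdlog),
                  cfg$age_range)
    wt_mu <- cfg$weight_slope * age + cfg$weight_intercept
    weight <- rtrunc(n, function(ix) {
      wt_mu[ix] * stats::rlnorm(length(ix), 0, cfg$weight_cv)
    }, cfg$weight_range)
    ddw <- rtrunc(n, function(ix) stats::rlnorm(length(ix),
                                                log(cfg$ddw_median),
                                                cfg$ddw_sdlog),
                  cfg$ddw_range)
    daily_dose <- pmax(round(ddw * weight / cfg$dose_rounding), 1) *
      cfg$dose_rounding
    albumin <- rtrunc(n, function(ix) rnorm(length(ix), cfg$albumin_mean,
                                            cfg$albumin_sd),
                      cfg$albumin_range)
    formulation <- sample(names(cfg$formulation_probs), n, replace = TRUE,
                          prob = cfg$formulation_probs)
    tibble::tibble(
      id = sprintf("S%04d", seq_len(n)),
      sex = ifelse(runif(n) < cfg$p_male, "male", "female"),
      age = age,
      weight = weight,
      albumin = albumin,
      daily_dose = daily_dose,
      daily_dose_per_kg = daily_dose / weight,
      formulation = formulation,
      cbz = runif(n) < cfg$p_cbz,
      pb = runif(n) < cfg$p_pb,
      pht = runif(n) < cfg$p_pht,
      ltg = runif(n) < cfg$p_ltg,
      clb = runif(n) < cfg$p_clb,
      other_comed = runif(n) < cfg$p_other_comed,
      uncontrolled_epilepsy = runif(n) < cfg$p_uncontrolled,
      pma = age * .weeks_per_year + 40
    )
  })
}

#' Generate steady-state dosing regimens and trough sampling design
#'
#' Splits each subject's daily dose into 1-3 equal administrations
#' (interdose interval 24, 12 or 8 h), flags the regimen as steady state,
#' and schedules one or two trough observations at the end of an interval.
#'
#' @param covariates Output of [generate_covariates()].
#' @param cfg The same [cohort_config()].
#' @return A `pk_dataset` design: dose rows plus observation rows with
#'   missing DV (`mdv = 1`), ready for [simulate_observations()].
#' @export
generate_regimens <- function(covariates, cfg = cohort_config()) {
  n <- nrow(covariates)
  des <- with_seed_maybe(cfg$seed + 1L, {
    tpd <- as.integer(sample(names(cfg$times_per_day_probs), n,
                             replace = TRUE,
                             prob = cfg$times_per_day_probs))
    n_samp <- if (is.null(cfg$samples_per_subject)) {
      1L + (runif(n) < cfg$p_second_sample)
    } else {
      rep(as.integer(cfg$samples_per_subject), n)
    }
    list(tpd = tpd, n_samp = n_samp)
  })
  ii <- 24 / des$tpd
  amt <- covariates$daily_dose / des$tpd
  rows <- purrr::map(seq_len(n), function(i) {
    obs_t <- ii[i] * c(10, 24)[seq_len(des$n_samp[i])]
    dplyr::bind_rows(
      tibble::tibble(id = covariates$id[i], time = 0, evid = 1L,
                     amt = amt[i], dv = NA_real_, mdv = 1L, ii = ii[i],
                     ss = 1L),
      tibble::tibble(id = covariates$id[i], time = obs_t, evid = 0L,
                     amt = NA_real_, dv = NA_real_, mdv = 1L,
                     ii = NA_real_, ss = 0L)
    )
  })
  ev <- dplyr::bind_rows(rows)
  ev <- dplyr::left_join(ev, covariates, by = "id")
  as_pk_dataset(ev, provenance = "synthetic cohort design")
}

#' Simulate observed concentrations under a truth model
#'
#' Draws individual parameters from the truth model's between-subject
#' distribution, evaluates the trough concentrations at the designed
#' sampling times, and applies the residual-error model (redrawing the rare
#' negative additive-error result so observations stay positive).
#' Observations below the limit of quantification are flagged in column
#' `bloq`, never dropped or imputed. The simulation-truth etas are stored
#' in `attr(x, "truth_etas")` for recovery audits.
#'
#' @param design A `pk_dataset` whose observation rows have missing DV.
#' @param truth Model id or `vpa_model` (library model or
#'   [binding_model()]).
#' @param seed Integer seed, or `NULL`.
#' @param loq Lower limit of quantification (mg/L).
#' @return The design with `dv` filled on observation rows (`mdv = 0`) and
#'   a logical `bloq` column.
#' @export
simulate_observations <- function(design, truth, seed = NULL, loq = 1) {
  spec <- model_spec(truth)
  des <- obs_design(design)
  cov <- subject_covariates(design)
  cov <- cov[match(des$ids, cov$id), ]
  typ <- typical_parameters(spec, cov)
  out <- design
  with_seed_maybe(seed, {
    eta <- draw_etas(spec, nrow(typ))
    ind <- typ
    for (nm in spec$eta) ind[[nm]] <- ind[[nm]] * exp(eta[, nm])
    pars <- expand_pars(ind, des)
    conc <- pred_structural(des, pars, spec$structural)
    conc <- spec$observation(conc, cov[des$obs$subj, ])
    dv <- residual_apply(spec, conc)
    bad <- which(dv <= 0)
    tries <- 0
    while (length(bad) && tries < 100) {
      dv[bad] <- residual_apply(spec, conc[bad])
      bad <- bad[dv[bad] <= 0]
      tries <- tries + 1
    }
    dv[dv <= 0] <- loq / 2   # unreachable in practice; last-resort floor
    out$dv[des$obs$row] <- dv
    out$mdv[des$obs$row] <- 0L
    out$bloq <- FALSE
    out$bloq[des$obs$row] <- dv < loq
    truth_etas <- tibble::tibble(id = des$ids)
    for (nm in spec$eta) truth_etas[[paste0("eta_", nm)]] <- eta[, nm]
    attr(out, "truth_etas") <- truth_etas
    attr(out, "truth_model") <- spec$id
  })
  out
}

#' Generate a complete synthetic TDM cohort
#'
#' Covariates, regimens and simulated observations in one call.
#'
#' @param cfg A [cohort_config()].
#' @return A `pk_dataset` with observed troughs, `bloq` flags and truth
#'   etas attached.
#' @export
simulate_cohort <- function(cfg = cohort_config()) {
  cov <- generate_covariates(cfg)
  design <- generate_regimens(cov, cfg)
  simulate_observations(design, cfg$truth_model, seed = cfg$seed + 2L,
                        loq = cfg$loq)
}
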