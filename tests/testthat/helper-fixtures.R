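# Shared fixtures, all generated in code.

# Covariate row of the "median child": 19 kg, 4.92 y, 23.44 mg/kg/day syrup
ref_covariates <- function(...) {
  base <- tibble::tibble(
    id = "S1", sex = "male", age = 4.92, weight = 19, albumin = 42.1,
    daily_dose = 19 * 23.44, daily_dose_per_kg = 23.44,
    formulation = "syrup", cbz = FALSE, pb = FALSE, pht = FALSE,
    ltg = FALSE, clb = FALSE, other_comed = FALSE,
    uncontrolled_epilepsy = FALSE, pma = 4.92 * 365.25 / 7 + 40
  )
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

# Steady-state design for given covariates: q12h dosing, troughs at the
# requested times after 5 days of dosing
make_design <- function(cov, obs_times = 120, tau = 12) {
  ev <- dplyr::bind_rows(
    tibble::tibble(id = cov$id, time = 0, evid = 1L,
                   amt = cov$daily_dose * tau / 24, dv = NA_real_,
                   mdv = 1L, ii = tau, ss = 1L),
    tidyr::expand_grid(id = cov$id, time = obs_times) |>
      dplyr::mutate(evid = 0L, amt = NA_real_, dv = NA_real_, mdv = 1L,
                    ii = NA_real_, ss = 0L)
  )
  ev <- dplyr::left_join(ev, cov, by = "id")
  as_pk_dataset(ev)
}

# Multi-observation single subject for MAP recovery exercises
make_rich_subject <- function(obs_offsets = c(1, 2, 4, 6, 8, 10, 11, 12)) {
  cov <- ref_covariates()
  ev <- dplyr::bind_rows(
    tibble::tibble(id = cov$id, time = 0, evid = 1L,
                   amt = cov$daily_dose / 2, dv = NA_real_, mdv = 1L,
                   ii = 12, ss = 1L),
    tibble::tibble(id = cov$id, time = 120 + obs_offsets, evid = 0L,
                   amt = NA_real_, dv = NA_real_, mdv = 1L, ii = NA_real_,
                   ss = 0L)
  )
  ev <- dplyr::left_join(ev, cov, by = "id")
  as_pk_dataset(ev)
}

# Fill a design's observations from a model at given etas (residual-free
# unless a perturbed spec is supplied)
fill_dv <- function(design, spec, eta = NULL, noise_sd = 0) {
  spec <- model_spec(spec)
  if (is.null(eta)) {
    ip <- population_predictions(design, spec)
    vals <- ip$pred
  } else {
    ip <- individual_predictions(design, spec, eta)
    vals <- ip$ipred
  }
  if (noise_sd > 0) vals <- vals + rnorm(length(vals), 0, noise_sd)
  design$dv[design$evid == 0] <- vals
  design$mdv[design$evid == 0] <- 0L
  design
}

# A model spec with variability switched off (degenerate simulation checks)
zero_variance_spec <- function(id) {
  spec <- model_spec(id)
  spec$omega[] <- 0
  spec$residual$value <- 0
  spec
}

# Write a minimal NONMEM-style CSV; returns the path
write_minimal_csv <- function(path = tempfile(fileext = ".csv")) {
  writeLines(c(
    "ID,TIME,AMT,DV,EVID,MDV,II,SS,WT,AGE,SEX,ALB,DD,FORM,CBZ,PB,PHT,LTG,CLB",
    "A1,0,250,.,1,1,12,1,19,4.92,male,42.1,500,syrup,0,0,0,0,0",
    "A1,120,.,55.2,0,0,.,0,19,4.92,male,42.1,500,syrup,0,0,0,0,0",
    "A1,132,.,60.1,0,0,.,0,19,4.92,male,42.1,500,syrup,0,0,0,0,0"
  ), path)
  path
}
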