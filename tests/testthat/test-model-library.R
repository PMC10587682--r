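test_that("typical parameters reproduce the printed covariate equations", {
  cov <- ref_covariates()
  p <- typical_parameters("serrano2019", cov)
  expect_equal(p$cl, 0.012 * 19^0.715 * 23.44^0.306, tolerance = 1e-12)
  expect_equal(p$cl, 0.2587, tolerance = 1e-3)
  expect_equal(p$v, 4.56)
  expect_equal(p$ka, 1.9)

  cov70 <- ref_covariates(weight = 70, age = 15, daily_dose = 70 * 23.44)
  expect_equal(typical_parameters("rodrigues", cov70)$cl, 0.624)
  expect_equal(typical_parameters("rodrigues", cov70)$v, 13.0)
  p22 <- typical_parameters("serrano2022", cov70)
  expect_equal(p22$cl, 0.646)
  expect_equal(p22$v, 14.0)
  expect_equal(p22$ka, 2.64)

  # Jiang at the reference age, no co-medication: 0.18 L/h
  expect_equal(round(typical_parameters("jiang", cov)$cl, 2), 0.18)
  # literal printed rendering gives the internally inconsistent ~1.08
  withr::with_options(list(vpaeval.jiang_literal = TRUE), {
    expect_equal(typical_parameters("jiang", cov)$cl, 1.0772, tolerance = 1e-4)
  })
})

test_that("every model yields positive parameters across the cohort covariate range", {
  grid <- tidyr::expand_grid(
    age = c(0.17, 2, 4.92, 15), wt_frac = c(0, 0.5, 1),
    ddw = c(8.7, 23.44, 57.69),
    formulation = c("syrup", "sustained_release")
  )
  grid$weight <- 4 + grid$wt_frac * (70 - 4)
  cov <- ref_covariates()[rep(1, nrow(grid)), ]
  cov$id <- sprintf("G%03d", seq_len(nrow(grid)))
  cov$age <- grid$age; cov$weight <- grid$weight
  cov$daily_dose <- grid$ddw * grid$weight
  cov$daily_dose_per_kg <- grid$ddw
  cov$formulation <- grid$formulation
  cov$pma <- cov$age * 365.25 / 7 + 40
  for (id in model_ids()) {
    p <- typical_parameters(id, cov)
    kin <- setdiff(names(p), "tlag")
    expect_true(all(as.matrix(p[kin]) > 0), label = paste(id, "positivity"))
  }
})

test_that("co-medication multipliers scale clearance by exactly the printed factor", {
  off <- ref_covariates()
  on <- ref_covariates(cbz = TRUE)
  expect_equal(typical_parameters("serrano2019", on)$cl /
                 typical_parameters("serrano2019", off)$cl, 1.359)
  expect_equal(typical_parameters("serrano2022", on)$cl /
                 typical_parameters("serrano2022", off)$cl, 1.521)
  expect_equal(typical_parameters("nakashima", ref_covariates(pht = TRUE))$cl /
                 typical_parameters("nakashima", off)$cl, 1.43)
  expect_equal(typical_parameters("gu", ref_covariates(ltg = TRUE))$cl /
                 typical_parameters("gu", off)$cl, 1.25)
})

test_that("absorption rules resolve by formulation and missing inputs error by name", {
  syrup <- typical_parameters("jiang", ref_covariates())
  sr <- typical_parameters("jiang", ref_covariates(formulation = "sustained_release"))
  expect_equal(syrup$ka, 0.251 + 2.24)
  expect_equal(sr$ka, 0.251)
  expect_error(
    typical_parameters("jiang", ref_covariates(formulation = NA_character_)),
    "absorption rule", class = "vpaeval_covariate_error")
  bad <- ref_covariates()
  bad$weight <- NA_real_
  bad$daily_dose_per_kg <- NA_real_
  expect_error(typical_parameters("serrano2019", bad), "weight",
               class = "vpaeval_covariate_error")
})

test_that("between-subject variability draws reproduce the printed CV", {
  cov <- ref_covariates()[rep(1, 10000), ]
  cov$id <- as.character(seq_len(nrow(cov)))
  ind <- sample_individual("serrano2019", cov, seed = 99)
  cv <- sd(ind$cl) / mean(ind$cl)
  expect_gt(cv, 0.214 * 0.9)
  expect_lt(cv, 0.214 * 1.1)

  # degenerate omega reduces to the typical value
  spec0 <- model_spec("serrano2019")
  spec0$omega[] <- 0
  ind0 <- sample_individual(spec0, ref_covariates(), seed = 1)
  expect_equal(ind0$cl, typical_parameters("serrano2019", ref_covariates())$cl)
  expect_equal(ind0$eta_cl, 0)

  # reproducibility by seed
  a <- sample_individual("gu", ref_covariates(), seed = 5)
  b <- sample_individual("gu", ref_covariates(), seed = 5)
  expect_identical(a, b)
})

test_that("correlated omega draws honor the printed covariance structure", {
  spec <- model_spec("ogungbenro")
  expect_equal(spec$omega["cl", "vc"], 0.0397)
  ev <- eigen(spec$omega, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  cov <- ref_covariates()[rep(1, 20000), ]
  cov$id <- as.character(seq_len(nrow(cov)))
  ind <- sample_individual(spec, cov, seed = 21)
  emp <- cov(cbind(ind$eta_cl, ind$eta_vc))[1, 2]
  expect_equal(emp, 0.0397, tolerance = 0.15)
})

test_that("residual error models reproduce the printed magnitudes", {
  x <- rep(50, 10000)
  add <- residual_apply("serrano2019", x, seed = 31)
  expect_equal(sd(add - 50), 15.6, tolerance = 0.05 * 15.6)
  prop <- residual_apply("ogungbenro", x, seed = 32)
  expect_equal(sd(prop), 50 * 0.348, tolerance = 0.05 * 50 * 0.348)

  spec0 <- model_spec("serrano2019")
  spec0$residual$value <- 0
  expect_equal(residual_apply(spec0, x, seed = 1), x)
  expect_error(residual_apply("serrano2019", c(-1, 5)),
               class = "vpaeval_domain_error")
})

test_that("the registry mirrors the library and exports to YAML", {
  reg <- model_registry()
  expect_identical(reg$id, model_ids())
  expect_identical(nrow(reg), 10L)
  expect_true(reg$unbound_scale[reg$id == "gu"])
  path <- tempfile(fileext = ".yaml")
  export_model_registry(path)
  y <- yaml::read_yaml(path)
  expect_identical(names(y), model_ids())
  expect_equal(y$serrano2019$residual$value, 15.6)
  expect_equal(y$ding$ka$syrup, 2.64)
})

test_that("clearance scaling produces an exact multiplicative comparator", {
  biased <- scale_model_clearance("serrano2019", 1.6)
  cov <- ref_covariates()
  expect_equal(typical_parameters(biased, cov)$cl,
               1.6 * typical_parameters("serrano2019", cov)$cl)
})
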