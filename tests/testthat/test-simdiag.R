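test_that("replicate simulation honors degeneracy, seeds and the analytic mean", {
  ds <- simulate_cohort(cohort_config(n_subjects = 40, seed = 3))
  # all variability off: every replicate equals PRED
  ens0 <- simulate_replicates(ds, zero_variance_spec("serrano2019"), k = 5,
                              seed = 1)
  for (r in 1:5) expect_equal(unname(ens0$sims[r, ]), ens0$pred)

  ens_a <- simulate_replicates(ds, "serrano2019", k = 50, seed = 7)
  ens_b <- simulate_replicates(ds, "serrano2019", k = 50, seed = 7)
  ens_c <- simulate_replicates(ds, "serrano2019", k = 50, seed = 8)
  expect_identical(ens_a$sims, ens_b$sims)
  expect_false(identical(ens_a$sims, ens_c$sims))

  # additive-error model: ensemble mean matches the analytic mean obtained
  # by quadrature over the clearance eta, observation by observation
  ens <- simulate_replicates(ds, "serrano2019", k = 2000, seed = 11)
  om <- sqrt(model_spec("serrano2019")$omega[1, 1])
  eta_grid <- seq(-5 * om, 5 * om, length.out = 401)
  w <- dnorm(eta_grid, 0, om)
  w <- w / sum(w)
  cov <- subject_covariates(ds)
  typ <- typical_parameters("serrano2019", cov)
  obs_rows <- ds[ds$evid == 0, ]
  expected <- vapply(seq_len(nrow(obs_rows)), function(j) {
    s <- match(obs_rows$id[j], cov$id)
    dose <- ds$amt[ds$evid == 1 & ds$id == obs_rows$id[j]][1]
    tau <- ds$ii[ds$evid == 1 & ds$id == obs_rows$id[j]][1]
    sum(w * conc_1cmt_ss(typ$cl[s] * exp(eta_grid), typ$v[s], typ$ka[s],
                         dose, tau, obs_rows$time[j]))
  }, numeric(1))
  mc_se <- apply(ens$sims, 2, sd) / sqrt(2000)
  expect_true(all(abs(colMeans(ens$sims) - expected) < 4.5 * mc_se))
})

test_that("npde matches its closed-form anchors", {
  ds <- simulate_cohort(cohort_config(n_subjects = 30, seed = 5,
                                      samples_per_subject = 1))
  ens <- simulate_replicates(ds, "serrano2019", k = 2000, seed = 13)
  # observation at the median of its simulated distribution: npde ~ 0
  med_obs <- apply(ens$sims, 2, median)
  r_med <- compute_npde(ens, obs = med_obs)
  expect_lt(max(abs(r_med$npde)), 0.05)
  # observation below every simulation: pde clamps at 1/(2k)
  # (simulated additive noise can dip below zero, so go under the minimum)
  r_low <- compute_npde(ens, obs = apply(ens$sims, 2, min) - 1)
  expect_equal(unique(r_low$pde), 1 / 4000)
  expect_equal(unique(r_low$npde), qnorm(1 / 4000), tolerance = 1e-10)
  expect_equal(round(unique(r_low$npde), 2), -3.48)
})

test_that("self-simulated data give calibrated npde", {
  ds <- simulate_cohort(cohort_config(n_subjects = 250, seed = 19,
                                      samples_per_subject = 1))
  ens <- simulate_replicates(ds, "serrano2019", k = 1000, seed = 21)
  r <- npde_tests(compute_npde(ens))
  n <- nrow(r)
  expect_lt(abs(mean(r$npde)), 3 / sqrt(n))
  v <- var(r$npde)
  band <- c(qchisq(0.005, n - 1), qchisq(0.995, n - 1)) / (n - 1)
  expect_gt(v, band[1]); expect_lt(v, band[2])
  expect_false(attr(r, "reject_global"))
})

test_that("the test battery flags gross location and scale violations", {
  ds <- simulate_cohort(cohort_config(n_subjects = 150, seed = 23,
                                      samples_per_subject = 1))
  ens <- simulate_replicates(ds, "serrano2019", k = 400, seed = 25)
  r <- compute_npde(ens)
  shifted <- r; shifted$npde <- r$npde + 1
  expect_lt(attr(npde_tests(shifted), "p_mean"), 1e-6)
  scaled <- r; scaled$npde <- r$npde * 2
  expect_lt(attr(npde_tests(scaled), "p_var"), 1e-6)
  tiny <- r[1:5, ]
  class(tiny) <- class(r)
  expect_error(npde_tests(tiny), class = "vpaeval_domain_error")
})

test_that("prediction correction and binning behave at their fixed points", {
  cov <- ref_covariates()[rep(1, 20), ]
  cov$id <- sprintf("T%02d", 1:20)
  ds <- make_design(cov, obs_times = 120)
  set.seed(4)
  ds$dv[ds$evid == 0] <- runif(20, 40, 70)
  ds$mdv[ds$evid == 0] <- 0L
  ens <- simulate_replicates(ds, "serrano2019", k = 100, seed = 2)
  # identical design: all PRED equal, correction factor is exactly 1
  res <- pcvpc(ens, n_bins = 1)
  expect_identical(dplyr::n_distinct(res$bin), 1L)
  obs_med <- res$observed[res$percentile == 50]
  expect_equal(obs_med, median(ds$dv[ds$evid == 0]))
  expect_true(all(res$sim_lo <= res$sim_hi))

  # mixed-interval cohort: observed median stays inside the simulated band
  # in nearly all bins under self-simulation
  ds2 <- simulate_cohort(cohort_config(n_subjects = 150, seed = 6))
  inside <- unlist(lapply(1:5, function(r) {
    e <- simulate_replicates(ds2, "serrano2019", k = 300, seed = 30 + r)
    p <- suppressMessages(pcvpc(e, n_bins = 3))
    med <- p[p$percentile == 50, ]
    med$observed >= med$sim_lo & med$observed <= med$sim_hi
  }))
  expect_gte(mean(inside), 0.9)
})
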