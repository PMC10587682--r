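test_that("steady-state trough matches the worked example and is linear in dose", {
  # 250 mg q12h, CL/F 0.2587 L/h, V/F 4.56 L, ka 1.9: trough ~57.9 mg/L
  trough <- conc_1cmt_ss(0.2587, 4.56, 1.9, 250, 12, 12)
  expect_equal(trough, 57.935, tolerance = 1e-4)
  expect_equal(conc_1cmt_ss(0.2587, 4.56, 1.9, 0, 12, 12), 0)
  expect_equal(conc_1cmt_ss(0.2587, 4.56, 1.9, 500, 12, 12), 2 * trough)
  expect_error(conc_1cmt_ss(-1, 4.56, 1.9, 250, 12, 12),
               class = "vpaeval_domain_error")
})

test_that("closed-form steady state equals 50-dose superposition over random draws", {
  set.seed(101)
  for (i in 1:100) {
    v <- runif(1, 3, 60)
    ke <- runif(1, 0.06, 0.5)   # elimination fast enough that 50 doses
    cl <- ke * v                # put the truncation error below 1e-9
    ka <- runif(1, max(0.1, 2 * ke), 4)
    tau <- sample(c(8, 12, 24), 1)
    tlag <- sample(c(0, 1), 1)
    dose <- runif(1, 50, 600)
    doses <- tibble::tibble(time = seq(0, by = tau, length.out = 50),
                            amount = dose)
    t_eval <- 49 * tau + runif(1, 0.2, tau)
    ss <- conc_1cmt_ss(cl, v, ka, dose, tau, t_eval, tlag)
    sup <- conc_superposition(list(cl = cl, v = v, ka = ka, tlag = tlag),
                              doses, t_eval)
    expect_lt(abs(ss - sup) / ss, 1e-6)
  }
})

test_that("superposition is commutative and reduces to the single-dose profile", {
  p <- list(cl = 0.26, v = 4.6, ka = 1.9)
  one <- tibble::tibble(time = 0, amount = 250)
  expect_equal(conc_superposition(p, one, 5),
               conc_1cmt_single(0.26, 4.6, 1.9, 250, 5))
  set.seed(2)
  doses <- tibble::tibble(time = runif(10, 0, 100), amount = runif(10, 50, 300))
  t_eval <- 120
  expect_equal(conc_superposition(p, doses, t_eval),
               conc_superposition(p, doses[sample(10), ], t_eval))
})

test_that("absorption-elimination degeneracy is continuous at ka = ke", {
  cl <- 0.3; v <- 10; ke <- cl / v
  at <- conc_1cmt_ss(cl, v, ke, 300, 12, 7)
  lo <- conc_1cmt_ss(cl, v, ke * (1 - 1e-9), 300, 12, 7)
  hi <- conc_1cmt_ss(cl, v, ke * (1 + 1e-9), 300, 12, 7)
  expect_lt(abs(lo - at) / at, 1e-6)
  expect_lt(abs(hi - at) / at, 1e-6)
  just_out <- conc_1cmt_ss(cl, v, ke * (1 + 1e-6), 300, 12, 7)
  expect_lt(abs(just_out - at) / at, 1e-4)
})

test_that("steady-state profile is non-negative with a single interior maximum", {
  set.seed(7)
  for (i in 1:20) {
    cl <- runif(1, 0.05, 1.5); v <- runif(1, 3, 50); ka <- runif(1, 0.2, 4)
    tt <- seq(0, 12, by = 0.02)
    prof <- conc_1cmt_ss(cl, v, ka, 300, 12, tt)
    expect_true(all(prof >= 0))
    d <- diff(prof)
    sign_changes <- sum(diff(sign(d[d != 0])) != 0)
    expect_lte(sign_changes, 1)
  }
})

test_that("two-compartment closed form degenerates to one compartment and obeys superposition", {
  c1 <- conc_1cmt_ss(0.854, 10.3, 2.0, 500, 12, 8)
  c2 <- conc_2cmt_ss(0.854, 10.3, 1e-6, 1e-9, 2.0, 500, 12, 8)
  expect_lt(abs(c1 - c2) / c1, 1e-4)

  set.seed(11)
  for (i in 1:100) {
    p <- list(cl = runif(1, 0.2, 2), vc = runif(1, 5, 20),
              vp = runif(1, 1, 10), q = runif(1, 0.5, 8),
              ka = runif(1, 0.3, 4), tlag = 0)
    tau <- 12
    # the slow hybrid constant dictates how many doses reach steady state
    k10 <- p$cl / p$vc; k12 <- p$q / p$vc; k21 <- p$q / p$vp
    b <- k10 + k12 + k21
    l2 <- (b - sqrt(b^2 - 4 * k10 * k21)) / 2
    n_dose <- max(60, ceiling(30 / (l2 * tau)))
    doses <- tibble::tibble(time = seq(0, by = tau, length.out = n_dose),
                            amount = 400)
    t_eval <- (n_dose - 1) * tau + runif(1, 0.2, tau)
    ss <- conc_2cmt_ss(p$cl, p$vc, p$vp, p$q, p$ka, 400, tau, t_eval)
    sup <- conc_superposition(p, doses, t_eval)
    expect_lt(abs(ss - sup) / ss, 1e-6)
    expect_equal(conc_2cmt_ss(p$cl, p$vc, p$vp, p$q, p$ka, 800, tau, 5),
                 2 * conc_2cmt_ss(p$cl, p$vc, p$vp, p$q, p$ka, 400, tau, 5))
  }
})

test_that("two-compartment solution matches numerical integration of the linear system", {
  skip_if_not_installed("deSolve")
  set.seed(13)
  p <- list(cl = runif(1, 0.3, 1.5), vc = runif(1, 6, 15),
            vp = runif(1, 2, 8), q = runif(1, 1, 6), ka = runif(1, 0.5, 3))
  rhs <- function(t, y, parms) {
    k10 <- p$cl / p$vc; k12 <- p$q / p$vc; k21 <- p$q / p$vp
    list(c(-p$ka * y[1],
           p$ka * y[1] - (k10 + k12) * y[2] + k21 * y[3],
           k12 * y[2] - k21 * y[3]))
  }
  sol <- deSolve::lsoda(c(500, 0, 0), seq(0, 24, by = 0.5), rhs, NULL,
                        rtol = 1e-10, atol = 1e-10)
  num <- sol[, 3] / p$vc
  ana <- conc_2cmt_single(p$cl, p$vc, p$vp, p$q, p$ka, 500, sol[, 1])
  expect_lt(max(abs(num[-1] - ana[-1]) / pmax(ana[-1], 1e-6)), 1e-5)
})

test_that("population predictions chain the covariate equations through the closed form", {
  cov <- ref_covariates(weight = 70, daily_dose = 1000, formulation = "syrup")
  ds <- make_design(cov, obs_times = 120, tau = 12)
  pp <- population_predictions(ds, "rodrigues")
  manual <- conc_1cmt_ss(0.624, 13.0, 0.274, 500, 12, 120)
  expect_equal(pp$pred, manual, tolerance = 1e-12)

  # PRED ignores the observed values and is deterministic
  ds2 <- ds
  ds2$dv[ds2$evid == 0] <- 99
  ds2$mdv[ds2$evid == 0] <- 0L
  expect_equal(population_predictions(ds2, "rodrigues")$pred, pp$pred)
  expect_equal(population_predictions(ds, "rodrigues")$pred, pp$pred)
})
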