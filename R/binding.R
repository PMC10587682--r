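#' Fixed constants of the protein-binding strategies
#'
#' Literature-fixed constants for the saturable-binding observation
#' functions and the dose-nonlinearity clearance models:
#' * one-binding-site model: `n_sites` (N) = 1.98 binding sites per albumin
#'   molecule, `k_assoc` (K) = 15.5 per mM;
#' * Langmuir equation: `kd` (Kd) = 7.8 mg/L, `bm` (Bm) = 130 mg/L;
#' * linear non-saturable equation: `kd_ns` = 2.12 mg/L, `bm_ns` = 67.3
#'   mg/L, `ns` (non-saturable slope) = 2.25;
#' * dose-dependent maximum-effect model: `emax` = 2.8, `gamma` = 1.68
#'   (with `dd50`, mg/kg/day, estimable);
#' * simple exponent model: reference daily dose 25 mg/kg/day (with the
#'   exponent `k_exp` estimable).
#'
#' @param ... Overrides for individual constants.
#' @return Named list of constants.
#' @export
binding_params <- function(...) {
  p <- list(
    n_sites = 1.98, k_assoc = 15.5,
    kd = 7.8, bm = 130,
    kd_ns = 2.12, bm_ns = 67.3, ns = 2.25,
    emax = 2.8, gamma = 1.68, dd50 = 37.4,
    dd_ref = 25, k_exp = NA_real_,
    mw_vpa = 144.21,   # g/mol, valproic acid
    mw_alb = 66500     # g/mol, human serum albumin
  )
  modifyList(p, list(...))
}

.binding_strategies <- c("one_site", "langmuir", "linear_ns")

#' Bound concentration from unbound, per binding strategy
#'
#' * `one_site`: saturable binding to N equivalent albumin sites,
#'   `Cb = N K Cu ALB / (1 + K Cu)` evaluated in molar units (the
#'   association constant is printed per mM) and converted back to mg/L;
#' * `langmuir`: `Cb = Bm Cu / (Kd + Cu)` in mg/L;
#' * `linear_ns`: Langmuir plus a linear non-saturable term,
#'   `Cb = Bm Cu / (Kd + Cu) + NS Cu` (its own Kd/Bm constants).
#'
#' Results are non-negative and monotone non-decreasing in `cu`.
#'
#' @param strategy One of `"one_site"`, `"langmuir"`, `"linear_ns"`.
#' @param cu Unbound concentration (mg/L), `>= 0`; vectorized.
#' @param alb Albumin (g/L); required for `one_site` only.
#' @param p Constants from [binding_params()].
#' @return Bound concentration (mg/L).
#' @export
bound_concentration <- function(strategy, cu, alb = NULL,
                                p = binding_params()) {
  strategy <- match.arg(strategy, .binding_strategies)
  if (any(cu < 0)) abort("`cu` must be non-negative.",
                         class = "vpaeval_domain_error")
  switch(strategy,
    one_site = {
      if (is.null(alb) || anyNA(alb)) {
        abort("`alb` (albumin, g/L) is required for the one-binding-site model.",
              class = "vpaeval_domain_error")
      }
      cu_mM <- cu / p$mw_vpa          # mg/L over g/mol -> mmol/L
      alb_mM <- alb * 1000 / p$mw_alb
      cb_mM <- p$n_sites * p$k_assoc * cu_mM * alb_mM /
        (1 + p$k_assoc * cu_mM)
      cb_mM * p$mw_vpa
    },
    langmuir = p$bm * cu / (p$kd + cu),
    linear_ns = p$bm_ns * cu / (p$kd_ns + cu) + p$ns * cu
  )
}

#' Total concentration from unbound
#'
#' `Ct = Cu + Cb(Cu)`; strictly increasing in `cu`.
#'
#' @inheritParams bound_concentration
#' @return Total concentration (mg/L).
#' @export
total_from_unbound <- function(strategy, cu, alb = NULL,
                               p = binding_params()) {
  cu + bound_concentration(strategy, cu, alb, p)
}

#' Unbound concentration from total (inverse observation function)
#'
#' Solves `total_from_unbound(cu) = ct` for the unique non-negative root by
#' safeguarded bisection/Newton on the strictly monotone forward map, to an
#' absolute tolerance of 1e-10 mg/L.
#'
#' @inheritParams bound_concentration
#' @param ct Total concentration (mg/L), `>= 0`; vectorized.
#' @return Unbound concentration (mg/L).
#' @export
unbound_from_total <- function(strategy, ct, alb = NULL,
                               p = binding_params()) {
  strategy <- match.arg(strategy, .binding_strategies)
  if (any(ct < 0)) abort("`ct` must be non-negative.",
                         class = "vpaeval_domain_error")
  n <- length(ct)
  if (!is.null(alb)) alb <- rep_len(alb, n)
  lo <- rep(0, n)
  hi <- pmax(ct, 1e-6)   # cu <= ct always (bound part non-negative)
  f <- function(x) total_from_unbound(strategy, x, alb, p) - ct
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    hi <- ifelse(fm >= 0, mid, hi)
    lo <- ifelse(fm >= 0, lo, mid)
    if (max(hi - lo) < 1e-12) break
  }
  out <- (lo + hi) / 2
  if (max(abs(f(out))) > 1e-8) {
    abort("Root-finding for unbound_from_total failed to converge.",
          class = "vpaeval_numeric_error")
  }
  out
}

#' Dose-nonlinear apparent clearance
#'
#' * `dde` (dose-dependent maximum effect):
#'   `CL = CLp * (1 + Emax * DDW^gamma / (DD50^gamma + DDW^gamma))`;
#' * `exponent` (simple exponent model): `CL = CLp * (DDW / 25)^k`.
#'
#' @param strategy `"dde"` or `"exponent"`.
#' @param clp Plasma clearance CLp (L/h), `> 0`.
#' @param ddw Daily dose (mg/kg/day), `>= 0`; vectorized.
#' @param p Constants from [binding_params()]; `dd50` for `dde`, `k_exp`
#'   for `exponent`.
#' @return Apparent clearance (L/h).
#' @export
nonlinear_clearance <- function(strategy, clp, ddw, p = binding_params()) {
  strategy <- match.arg(strategy, c("dde", "exponent"))
  stopifnot_positive(clp = clp)
  if (any(ddw < 0)) abort("`ddw` must be non-negative.",
                          class = "vpaeval_domain_error")
  switch(strategy,
    dde = clp * (1 + p$emax * ddw^p$gamma / (p$dd50^p$gamma + ddw^p$gamma)),
    exponent = clp * (ddw / p$dd_ref)^p$k_exp
  )
}
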