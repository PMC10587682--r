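.binding_variants <- c("model_I", "model_II", "model_III", "model_IV",
                       "model_V")

.variant_strategy <- c(model_I = "one_site", model_II = "langmuir",
                       model_III = "dde", model_IV = "linear_ns",
                       model_V = "exponent")

# Unbound-scale variants: structural compartment tracks free drug, the
# observation function maps unbound -> total
.variant_unbound <- c(model_I = TRUE, model_II = TRUE, model_III = FALSE,
                      model_IV = TRUE, model_V = FALSE)

#' Construct a protein-binding popPK model as a `vpa_model`
#'
#' Builds one of the five protein-binding modeling strategies as a complete
#' population model usable everywhere a library model is: a one-compartment
#' first-order-absorption base with
#' * `model_I` (one-binding-site), `model_II` (Langmuir), `model_IV`
#'   (linear non-saturable): the structural compartment tracks unbound drug
#'   (parameters CLu/F, Vu/F) and the fixed-constant binding equation maps
#'   unbound to the observed total concentration;
#' * `model_III` (dose-dependent maximum effect) and `model_V` (simple
#'   exponent): total-concentration kinetics with the daily dose entering
#'   the clearance model.
#'
#' Clearance scales allometrically on weight (exponent 0.75) and volume
#' linearly, both referenced to 19 kg (the pediatric cohort median).
#' Between-subject variability is a lognormal eta on clearance; residual
#' error is proportional. Absorption is fixed by formulation (syrup 2.64,
#' sustained release 0.46 per hour).
#'
#' @param variant One of `"model_I"` .. `"model_V"`.
#' @param clp Typical clearance at 19 kg (L/h): unbound-scale CLu/F for
#'   variants I/II/IV, plasma CLp/F for III/V.
#' @param v Typical volume at 19 kg (L): Vu/F for I/II/IV, V/F for III/V.
#' @param k Daily-dose exponent (model V only).
#' @param dd50 Half-effect daily dose, mg/kg/day (model III only).
#' @param omega SD of the lognormal clearance eta.
#' @param sigma Proportional residual SD (fraction).
#' @param bp Binding constants, [binding_params()].
#' @return A `vpa_model`.
#' @export
binding_model <- function(variant, clp, v, k = 0.3, dd50 = 37.4,
                          omega = 0.3, sigma = 0.1, bp = binding_params()) {
  variant <- match.arg(variant, .binding_variants)
  stopifnot_positive(clp = clp, v = v)
  strategy <- .variant_strategy[[variant]]
  bp$dd50 <- dd50
  bp$k_exp <- k
  required <- switch(variant,
    model_I = c("weight", "albumin"),
    model_III = c("weight", "daily_dose_per_kg"),
    model_V = c("weight", "daily_dose_per_kg"),
    c("weight"))
  typical <- function(cov) {
    cl <- clp * (cov$weight / 19)^0.75
    if (variant %in% c("model_III", "model_V")) {
      cl <- nonlinear_clearance(strategy, cl, cov$daily_dose_per_kg, bp)
    }
    tibble::tibble(cl = cl, v = v * (cov$weight / 19))
  }
  observation <- if (.variant_unbound[[variant]]) {
    function(conc, cov) total_from_unbound(strategy, conc, cov$albumin, bp)
  } else {
    function(conc, cov) conc
  }
  spec <- list(
    id = paste0("binding_", variant),
    label = sprintf("Protein-binding strategy %s (%s)", variant, strategy),
    structural = "1cmt",
    required = required,
    typical = typical,
    ka_rule = .ka_map(
      ka = setNames(c(2.64, 2.64, 1.57, 1.57, 0.46, 0.46), .formulations),
      printed = "syrup 2.64, conventional tablet 1.57, SR tablet 0.46"),
    eta = "cl",
    omega = matrix(omega^2, 1, 1, dimnames = list("cl", "cl")),
    residual = list(type = "proportional", value = sigma),
    observation = observation,
    variant = variant,
    binding = bp,
    theta = list(clp = clp, v = v, k = k, dd50 = dd50, omega = omega,
                 sigma = sigma)
  )
  class(spec) <- "vpa_model"
  spec
}
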