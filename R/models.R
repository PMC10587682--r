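#' @name model_library
#' @title Library of published pediatric valproate population PK models
#'
#' @description
#' Ten published population pharmacokinetic models of valproic acid in
#' children with epilepsy, encoded behind one uniform interface: the printed
#' covariate equations for the typical parameters, fixed-effect values,
#' between-subject variability (lognormal random effects), residual-error
#' model (additive in mg/L or proportional), and formulation-specific
#' absorption rules. Model identifiers:
#' `serrano2019`, `eldesoky`, `jiang`, `silva`, `ogungbenro`, `nakashima`,
#' `ding`, `rodrigues`, `gu`, `serrano2022`.
#'
#' Conventions:
#' * Printed CV% variability becomes a lognormal eta with `omega = CV/100`
#'   (set `options(vpaeval.bsv_convention = "exact")` for
#'   `omega = sqrt(log(1 + CV^2))`, which differs by <3% at these
#'   magnitudes). Entries printed as variances are used as variances.
#' * Residual entries printed in mg/L are additive; entries printed in %
#'   are proportional.
#' * Absorption constants printed for formulations absent from a dataset are
#'   filled by release class (liquid forms take the fastest printed rate,
#'   sustained/delayed-release the slowest, immediate-release solids an
#'   intermediate one); the registry marks which entries are printed and
#'   which are class-mapped.
#' * The `gu` model parameterizes unbound drug (hence its very large
#'   apparent volume); its observation function maps unbound to total
#'   concentration through the linear non-saturable binding equation.
#' * The `jiang` clearance equation is used in the internally consistent
#'   multiplicative form `0.106 * 0.98^CO + 0.0157 * AGE` (typical CL/F
#'   0.18 L/h at the reference age 4.92 y); the literal rendering
#'   `0.106^(0.98*CO) + 0.0157*AGE` is available via
#'   `options(vpaeval.jiang_literal = TRUE)`.
#' * The `ding` weight exponent declines with age,
#'   `0.791 - 0.096 * AGE^8.63 / (th50^8.63 + AGE^8.63)`; `th50` defaults to
#'   0.802 years and can be overridden via `options(vpaeval.ding_th50 = )`.
NULL

.ka_all <- function(value, tlag = 0) {
  list(ka = setNames(rep(value, length(.formulations)), .formulations),
       tlag = setNames(rep(tlag, length(.formulations)), .formulations),
       printed = "all formulations")
}

.ka_map <- function(ka, tlag = NULL, printed = NULL) {
  list(ka = ka[.formulations],
       tlag = if (is.null(tlag)) setNames(rep(0, length(.formulations)),
                                          .formulations)
              else tlag[.formulations],
       printed = printed)
}

.need <- function(cov, cols, id) {
  for (nm in cols) {
    if (!nm %in% names(cov) || anyNA(cov[[nm]])) {
      abort(sprintf("Model '%s' requires covariate '%s' (missing or NA).",
                    id, nm), class = "vpaeval_covariate_error")
    }
  }
}

.jiang_co <- function(cov) {
  as.numeric(cov$cbz | cov$pb | cov$pht | cov$ltg | cov$clb |
               cov$other_comed)
}

.model_defs <- function() {
  forms <- .formulations
  list(
    serrano2019 = list(
      label = "Serrano et al. 2019 (Spain, 1CMT, FPIA)",
      structural = "1cmt",
      required = c("weight", "daily_dose_per_kg", "cbz"),
      typical = function(cov) {
        tibble::tibble(
          cl = 0.012 * cov$weight^0.715 * cov$daily_dose_per_kg^0.306 *
            ifelse(cov$cbz, 1.359, 1),
          v = 0.24 * cov$weight
        )
      },
      ka_rule = .ka_all(1.9),
      eta = "cl",
      omega_cv = c(cl = 21.4),
      residual = list(type = "additive", value = 15.6)
    ),
    eldesoky = list(
      label = "El-Desoky et al. (Egypt, 1CMT, FPIA)",
      structural = "1cmt",
      required = c("daily_dose", "age", "cbz", "uncontrolled_epilepsy"),
      typical = function(cov) {
        cl <- 0.105 + 0.000248 * cov$daily_dose + 0.0968 * cov$age / 20 +
          0.151 * as.numeric(cov$cbz) +
          0.0803 * as.numeric(cov$uncontrolled_epilepsy)
        if (any(cl < 1e-6)) {
          warn("El-Desoky clearance floored at 1e-6 L/h for some subjects.")
          cl <- pmax(cl, 1e-6)
        }
        tibble::tibble(cl = cl, v = 11.5)
      },
      ka_rule = .ka_map(
        ka = setNames(c(4, 4, 1, 1, 1, 1), forms),
        printed = "syrup 4, enteric-coated tablet 1"),
      eta = "cl",
      omega_cv = c(cl = 23.6),
      residual = list(type = "additive", value = 5.24)
    ),
    jiang = list(
      label = "Jiang et al. (China, 1CMT, FPIA)",
      structural = "1cmt",
      required = c("age", "weight"),
      typical = function(cov) {
        co <- .jiang_co(cov)
        cl <- if (isTRUE(getOption("vpaeval.jiang_literal", FALSE))) {
          0.106^(0.98 * co) + 0.0157 * cov$age
        } else {
          0.106 * 0.98^co + 0.0157 * cov$age
        }
        tibble::tibble(cl = cl, v = 2.88 + 0.157 * cov$weight)
      },
      # ka = 0.251 + 2.24 * (1 - HS); HS = 1 for sustained release
      ka_rule = .ka_map(
        ka = setNames(c(2.491, 2.491, 2.491, 2.491, 2.491, 0.251), forms),
        printed = "sustained release 0.251, otherwise 2.491"),
      eta = c("cl", "v", "ka"),
      omega_cv = c(cl = 25.1, v = 49.1, ka = 11.0),
      residual = list(type = "additive", value = 13.2)
    ),
    silva = list(
      label = "Silva Alves et al. (Mexico, 1CMT, CEDIA)",
      structural = "1cmt",
      required = c("weight", "daily_dose", "pb"),
      typical = function(cov) {
        tibble::tibble(
          cl = (0.0466 + 0.00363 * cov$weight + 0.000282 * cov$daily_dose) *
            ifelse(cov$pb, 1.236, 1),
          v = 0.24 * cov$weight
        )
      },
      ka_rule = .ka_all(1.2),
      eta = "cl",
      omega_cv = c(cl = 14.1),
      residual = list(type = "additive", value = 17.3)
    ),
    ogungbenro = list(
      label = "Ogungbenro & Aarons (United States, 2CMT, FPIA)",
      structural = "2cmt",
      required = c("weight", "age"),
      typical = function(cov) {
        tibble::tibble(
          cl = 0.854 * (cov$weight / 70)^0.75,
          vc = 10.3 * (cov$weight / 70) * (cov$age / 8.5)^(-0.267),
          vp = 4.08 * (cov$weight / 70),
          q = 5.34 * (cov$weight / 70)^0.75
        )
      },
      ka_rule = .ka_map(
        ka = setNames(c(4.1, 1.2, 2.0, 4.1, 4.1, 1.2), forms),
        tlag = setNames(c(0, 1.0, 0, 2.0, 2.0, 1.0), forms),
        printed = "capsule 2.0, sprinkle 1.2, tablet 4.1; tlag sprinkle 1.0, tablet 2.0"),
      eta = c("cl", "vc", "vp"),
      omega_cv = c(cl = 35.9, vc = 19.6, vp = 101.5),
      # printed omega covariances: CL~Vc, CL~Vp, Vc~Vp
      omega_cov = c(cl.vc = 0.0397, cl.vp = 0.0777, vc.vp = 0.144),
      residual = list(type = "proportional", value = 0.348)
    ),
    nakashima = list(
      label = "Nakashima et al. (Japan, 1CMT, EMIT)",
      structural = "1cmt",
      required = c("daily_dose", "sex", "cbz", "pb", "pht", "clb"),
      typical = function(cov) {
        tibble::tibble(
          cl = 0.559 * (cov$daily_dose / 1000)^0.596 *
            ifelse(cov$sex == "female", 0.917, 1) *
            ifelse(cov$cbz, 1.19, 1) * ifelse(cov$pb, 1.12, 1) *
            ifelse(cov$pht, 1.43, 1) * ifelse(cov$clb, 0.906, 1),
          v = 21.4 * (cov$daily_dose / 1000)^1.52
        )
      },
      ka_rule = .ka_all(0.109, tlag = 3.0),
      eta = c("cl", "v", "ka"),
      omega_cv = c(cl = 24.2),
      # V and ka variability printed as eta variances, not CV%
      omega_var = c(v = 0.043, ka = 0.088),
      residual = list(type = "proportional", value = 0.248)
    ),
    ding = list(
      label = "Ding et al. (China, 1CMT, FPIA)",
      structural = "1cmt",
      required = c("weight", "age", "daily_dose_per_kg", "cbz",
                   "formulation"),
      typical = function(cov) {
        th50 <- getOption("vpaeval.ding_th50", 0.802)
        expo <- 0.791 - 0.096 * cov$age^8.63 / (th50^8.63 + cov$age^8.63)
        ddw <- cov$daily_dose_per_kg
        tibble::tibble(
          cl = 0.3 * ifelse(cov$cbz, 1.43, 1) * (cov$weight / 70)^expo *
            (1 + 2.8 * ddw^1.68 / (37.4^1.68 + ddw^1.68)),
          v = 22.2 * (cov$weight / 70)
        )
      },
      ka_rule = .ka_map(
        ka = setNames(c(2.64, 2.64, 1.57, 1.57, 0.46, 0.46), forms),
        printed = "syrup 2.64, conventional tablet 1.57, SR tablet 0.46"),
      eta = "cl",
      omega_cv = c(cl = 19.5),
      residual = list(type = "additive", value = 13.3)
    ),
    rodrigues = list(
      label = "Rodrigues et al. (France, 1CMT, FPIA)",
      structural = "1cmt",
      required = c("weight"),
      typical = function(cov) {
        tibble::tibble(cl = 0.624 * (cov$weight / 70)^0.75,
                       v = 13.0 * (cov$weight / 70))
      },
      ka_rule = .ka_all(0.274),
      eta = "cl",
      omega_cv = c(cl = 33.9),
      residual = list(type = "proportional", value = 0.154)
    ),
    gu = list(
      label = "Gu et al. (China, 1CMT unbound, GC)",
      structural = "1cmt",
      required = c("weight", "pma", "ltg"),
      typical = function(cov) {
        tibble::tibble(
          cl = 10.4 * ifelse(cov$ltg, 1.25, 1) * (cov$weight / 70)^0.75 *
            cov$pma^4.17 / (33.7^4.17 + cov$pma^4.17),
          v = 1680.1 * (cov$weight / 70)
        )
      },
      ka_rule = .ka_map(
        ka = setNames(c(2.64, 2.64, 1.57, 1.57, 0.46, 0.46), forms),
        printed = "syrup 2.64, conventional tablet 1.57, SR tablet 0.46"),
      eta = c("cl", "v"),
      omega_cv = c(cl = 43.0, v = 92.8),
      residual = list(type = "proportional", value = 0.025),
      # structural compartment tracks unbound drug; observed concentration
      # is total via the linear non-saturable binding equation
      observation = function(conc, cov) {
        total_from_unbound("linear_ns", conc)
      }
    ),
    serrano2022 = list(
      label = "Serrano et al. 2022 (Spain, 1CMT, FPIA)",
      structural = "1cmt",
      required = c("weight", "age", "pht", "pb", "cbz"),
      typical = function(cov) {
        tibble::tibble(
          cl = 0.646 * (cov$weight / 70)^0.75 * (cov$age / 15.0)^(-0.0154) *
            ifelse(cov$pht, 1.640, 1) * ifelse(cov$pb, 1.386, 1) *
            ifelse(cov$cbz, 1.521, 1),
          v = 14.0 * (cov$weight / 70)
        )
      },
      ka_rule = .ka_map(
        ka = setNames(c(2.64, 2.64, 0.78, 0.78, 0.78, 0.38), forms),
        printed = "syrup 2.64, EC tablet 0.78, SR tablet 0.38"),
      eta = "cl",
      omega_cv = c(cl = 26.8),
      residual = list(type = "proportional", value = 0.577)
    )
  )
}

#' Identifiers of the library models
#' @return Character vector of model ids.
#' @export
model_ids <- function() names(.model_defs())

#' Retrieve one model specification
#'
#' @param id Model identifier (see [model_ids()]), or a `vpa_model` object
#'   (returned unchanged).
#' @return A `vpa_model` object: list with elements `id`, `label`,
#'   `structural`, `typical` (covariates -> typical parameters), `ka_rule`,
#'   `eta` (parameters carrying random effects), `omega` (covariance matrix
#'   of the etas), `residual`, and `observation` (structural-to-observed
#'   concentration map; identity unless the model predicts unbound drug).
#' @export
model_spec <- function(id) {
  if (inherits(id, "vpa_model")) return(id)
  defs <- .model_defs()
  if (!id %in% names(defs)) {
    abort(sprintf("Unknown model id '%s'. Valid ids: %s", id,
                  paste(names(defs), collapse = ", ")),
          class = "vpaeval_config_error")
  }
  def <- defs[[id]]
  def$id <- id
  def$omega <- .build_omega(def)
  def$observation <- def$observation %||% function(conc, cov) conc
  class(def) <- "vpa_model"
  def
}

.build_omega <- function(def) {
  eta <- def$eta
  conv <- getOption("vpaeval.bsv_convention", "cv")
  om <- setNames(numeric(length(eta)), eta)
  for (nm in eta) {
    if (!is.null(def$omega_var) && nm %in% names(def$omega_var)) {
      om[nm] <- sqrt(def$omega_var[[nm]])
    } else {
      cv <- def$omega_cv[[nm]] / 100
      om[nm] <- if (conv == "exact") sqrt(log(1 + cv^2)) else cv
    }
  }
  O <- diag(om^2, nrow = length(eta))
  dimnames(O) <- list(eta, eta)
  if (!is.null(def$omega_cov)) {
    for (nm in names(def$omega_cov)) {
      pair <- strsplit(nm, ".", fixed = TRUE)[[1]]
      O[pair[1], pair[2]] <- O[pair[2], pair[1]] <- def$omega_cov[[nm]]
    }
  }
  O
}

#' Typical (population) PK parameters for given covariates
#'
#' Evaluates the model's printed covariate equations with all random effects
#' at zero. Co-medication multipliers apply only where the corresponding flag
#' is set; the absorption constant (and lag) is resolved from the
#' formulation.
#'
#' @param model Model id or `vpa_model`.
#' @param covariates Data frame of covariates, one row per subject. Columns
#'   as in [subject_covariates()]; `daily_dose_per_kg` and `pma` are derived
#'   when absent but derivable.
#' @return Tibble, one row per covariate row: `cl`, `v` (or `vc`, `vp`, `q`),
#'   `ka`, `tlag`.
#' @export
typical_parameters <- function(model, covariates) {
  spec <- model_spec(model)
  cov <- tibble::as_tibble(covariates)
  if (!"daily_dose_per_kg" %in% names(cov) &&
      all(c("daily_dose", "weight") %in% names(cov))) {
    cov$daily_dose_per_kg <- cov$daily_dose / cov$weight
  }
  if (("pma" %in% spec$required) && (!"pma" %in% names(cov) ||
                                     anyNA(cov$pma))) {
    if ("age" %in% names(cov) && !anyNA(cov$age)) {
      cov$pma <- cov$age * .weeks_per_year + 40
    }
  }
  .need(cov, spec$required, spec$id)
  pars <- spec$typical(cov)
  form <- cov$formulation %||% rep(NA_character_, nrow(cov))
  ka <- spec$ka_rule$ka[form]
  tlag <- spec$ka_rule$tlag[form]
  if (is.null(cov$formulation)) {
    # fixed-ka models do not depend on the formulation
    if (length(unique(spec$ka_rule$ka)) == 1L) {
      ka <- rep(spec$ka_rule$ka[[1]], nrow(cov))
      tlag <- rep(spec$ka_rule$tlag[[1]], nrow(cov))
    }
  }
  if (anyNA(ka)) {
    abort(sprintf("Model '%s' has no absorption rule for formulation(s): %s",
                  spec$id,
                  paste(unique(form[is.na(ka)]), collapse = ", ")),
          class = "vpaeval_covariate_error")
  }
  pars$ka <- unname(ka)
  pars$tlag <- unname(tlag)
  kin <- setdiff(names(pars), "tlag")
  if (any(as.matrix(pars[kin]) <= 0)) {
    abort(sprintf("Model '%s': non-positive typical parameter for the supplied covariates.",
                  spec$id), class = "vpaeval_domain_error")
  }
  pars
}

#' Sample individual PK parameters (random effects included)
#'
#' Draws one eta vector per covariate row from a zero-mean multivariate
#' normal with the model's omega matrix (correlations honored where printed)
#' and applies them as `typical * exp(eta)` on the affected parameters.
#'
#' @inheritParams typical_parameters
#' @param seed Integer seed, or `NULL` to use the active RNG stream.
#' @return Tibble of individual parameters with the eta draws attached as
#'   columns `eta_<parameter>`.
#' @export
sample_individual <- function(model, covariates, seed = NULL) {
  spec <- model_spec(model)
  pars <- typical_parameters(spec, covariates)
  n <- nrow(pars)
  eta <- with_seed_maybe(seed, draw_etas(spec, n))
  for (nm in spec$eta) {
    pars[[nm]] <- pars[[nm]] * exp(unname(eta[, nm]))
    pars[[paste0("eta_", nm)]] <- unname(eta[, nm])
  }
  pars
}

draw_etas <- function(spec, n) {
  p <- length(spec$eta)
  if (all(spec$omega == 0)) {
    eta <- matrix(0, n, p)
  } else {
    eta <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = spec$omega)
    if (n == 1) eta <- matrix(eta, 1, p)
  }
  colnames(eta) <- spec$eta
  eta
}

#' Apply the model's residual-error model to concentrations
#'
#' Additive models add `N(0, sigma^2)` noise in mg/L; proportional models
#' multiply by `(1 + eps)` with `eps ~ N(0, sigma^2)` and sigma the printed
#' fraction.
#'
#' @param model Model id or `vpa_model`.
#' @param conc Concentrations (mg/L), `>= 0`.
#' @param seed Integer seed, or `NULL`.
#' @return Perturbed concentrations (mg/L); may be negative for additive
#'   noise near zero (callers that need positivity should resample).
#' @export
residual_apply <- function(model, conc, seed = NULL) {
  spec <- model_spec(model)
  if (any(conc < 0)) abort("`conc` must be non-negative.",
                           class = "vpaeval_domain_error")
  with_seed_maybe(seed, {
    eps <- rnorm(length(conc))
    if (spec$residual$type == "additive") {
      conc + spec$residual$value * eps
    } else {
      conc * (1 + spec$residual$value * eps)
    }
  })
}

#' Scale a model's typical clearance by a fixed factor
#'
#' Returns a modified copy of the model whose typical CL/F is multiplied by
#' `factor` — the standard construction for misspecification and power
#' studies (a biased-clearance comparator).
#'
#' @param model Model id or `vpa_model`.
#' @param factor Positive multiplier on CL/F.
#' @return A `vpa_model`.
#' @export
scale_model_clearance <- function(model, factor) {
  spec <- model_spec(model)
  stopifnot_positive(factor = factor)
  base_typical <- spec$typical
  spec$typical <- function(cov) {
    p <- base_typical(cov)
    p$cl <- p$cl * factor
    p
  }
  spec$id <- paste0(spec$id, "_clx", format(factor))
  spec$label <- paste0(spec$label, sprintf(" [CL x %s]", format(factor)))
  spec
}

#' Human-readable registry of the model library
#'
#' @return Tibble with one row per model: structure, variability, residual
#'   error and absorption-rule summaries. Use [export_model_registry()] for a
#'   YAML mirror auditable outside R.
#' @export
model_registry <- function() {
  purrr::map_dfr(model_ids(), function(id) {
    s <- model_spec(id)
    tibble::tibble(
      id = id,
      label = s$label,
      structural = s$structural,
      eta_parameters = paste(s$eta, collapse = ", "),
      bsv = paste(sprintf("%s=%.3g", s$eta, sqrt(diag(s$omega))),
                  collapse = ", "),
      residual_type = s$residual$type,
      residual_value = s$residual$value,
      ka_printed = s$ka_rule$printed %||% "fixed",
      unbound_scale = !is.null(.model_defs()[[id]]$observation)
    )
  })
}

#' Export the model registry as YAML
#'
#' Writes every fixed-effect equation input, variability term, residual
#' error and absorption rule in plain text so the encoded values can be
#' audited without reading code.
#'
#' @param path Output file (`.yaml`).
#' @return `path`, invisibly.
#' @export
export_model_registry <- function(path) {
  defs <- .model_defs()
  out <- purrr::map(model_ids(), function(id) {
    s <- model_spec(id)
    list(
      label = s$label,
      structural = s$structural,
      typical_equations = paste(deparse(body(defs[[id]]$typical)),
                                collapse = "\n"),
      ka = as.list(s$ka_rule$ka),
      tlag = as.list(s$ka_rule$tlag),
      ka_printed = s$ka_rule$printed,
      omega = apply(s$omega, 1, as.list),
      residual = s$residual
    )
  })
  names(out) <- model_ids()
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.vpa_model <- function(x, ...) {
  cat(sprintf("<vpa_model> %s: %s\n", x$id, x$label))
  cat(sprintf("  structural: %s; etas on: %s; residual: %s %s\n",
              x$structural, paste(x$eta, collapse = ", "),
              x$residual$type, format(x$residual$value)))
  invisible(x)
}
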