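#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a binding-model fit
#'
#' @param x A `binding_fit`.
#' @param ... Unused.
#' @return Tibble with one row per estimated parameter: `term`, `estimate`,
#'   `fixed`.
#' @export
tidy.binding_fit <- function(x, ...) {
  est <- c(x$estimates, x$fixed)
  tibble::tibble(term = names(est),
                 estimate = unlist(est),
                 fixed = names(est) %in% names(x$fixed))
}

#' One-row summary of a binding-model fit
#'
#' @param x A `binding_fit`.
#' @param ... Unused.
#' @return Tibble: `variant`, `ofv`, `converged`, `n_subjects`, `n_obs`,
#'   `seed`.
#' @export
glance.binding_fit <- function(x, ...) {
  tibble::tibble(variant = x$variant, ofv = x$ofv,
                 converged = x$converged, n_subjects = x$n_subjects,
                 n_obs = x$n_obs, seed = x$seed)
}

#' One-row summary of an npde result after testing
#'
#' @param x An `npde_result` processed by [npde_tests()].
#' @param ... Unused.
#' @return Tibble: `n`, `mean_npde`, `var_npde`, `p_mean`, `p_var`,
#'   `p_norm`, `p_global`, `reject_global`.
#' @export
glance.npde_result <- function(x, ...) {
  tibble::tibble(
    n = nrow(x),
    mean_npde = mean(x$npde),
    var_npde = var(x$npde),
    p_mean = attr(x, "p_mean") %||% NA_real_,
    p_var = attr(x, "p_var") %||% NA_real_,
    p_norm = attr(x, "p_norm") %||% NA_real_,
    p_global = attr(x, "p_global") %||% NA_real_,
    reject_global = attr(x, "reject_global") %||% NA
  )
}

#' Tidy prediction-error values from an evaluation
#'
#' Unnests the per-observation prediction errors of a
#' [evaluate_predictions()] result into long format, ready for boxplots or
#' cumulative-distribution plots.
#'
#' @param x A `vpa_evaluation`.
#' @param ... Unused.
#' @return Tibble: `model`, `pe`.
#' @export
tidy.vpa_evaluation <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::select("model", "pe_values") |>
    tidyr::unnest("pe_values") |>
    dplyr::rename(pe = "pe_values")
}
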