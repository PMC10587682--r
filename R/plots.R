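#' @importFrom ggplot2 autoplot ggplot aes geom_boxplot geom_hline
#'   geom_point geom_ribbon geom_line geom_qq geom_qq_line labs
#'   scale_y_continuous facet_wrap stat_ecdf geom_abline
#' @export
ggplot2::autoplot

#' Prediction-error boxplots per model
#'
#' Boxplots of PE% with reference lines at 0 and +/-30%, the usual display
#' of prediction-based external-evaluation results.
#'
#' @param object A `vpa_evaluation` from [evaluate_predictions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vpa_evaluation <- function(object, ...) {
  long <- tidy.vpa_evaluation(object)
  ggplot(long, aes(x = .data$model, y = .data$pe)) +
    geom_hline(yintercept = 0, linewidth = 0.3) +
    geom_hline(yintercept = c(-30, 30), linetype = "dotted",
               colour = "steelblue") +
    geom_boxplot(outlier.size = 0.6) +
    labs(x = NULL, y = "Prediction error (%)") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Cumulative distribution of absolute prediction errors
#'
#' @param object A `vpa_evaluation`.
#' @return A ggplot object.
#' @export
plot_pe_cdf <- function(object) {
  long <- tidy.vpa_evaluation(object)
  ggplot(long, aes(x = abs(.data$pe), colour = .data$model)) +
    stat_ecdf() +
    ggplot2::coord_cartesian(xlim = c(0, 100)) +
    labs(x = "|Prediction error| (%)", y = "Cumulative fraction") +
    ggplot2::theme_bw()
}

#' Normal quantile-quantile plot of npde values
#'
#' @param object An `npde_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.npde_result <- function(object, ...) {
  ggplot(tibble::as_tibble(object), aes(sample = .data$npde)) +
    geom_qq_line(colour = "steelblue") +
    geom_qq(size = 0.7) +
    labs(x = "Standard normal quantiles", y = "npde") +
    ggplot2::theme_bw()
}

#' Prediction-corrected VPC ribbon plot
#'
#' Observed percentiles of prediction-corrected concentrations against the
#' simulated confidence bands per bin.
#'
#' @param object A `pcvpc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pcvpc_result <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$t_mid <- (d$t_lo + d$t_hi) / 2
  ggplot(d, aes(x = .data$t_mid, group = .data$percentile)) +
    geom_ribbon(aes(ymin = .data$sim_lo, ymax = .data$sim_hi),
                fill = "steelblue", alpha = 0.25) +
    geom_line(aes(y = .data$sim_mid), colour = "steelblue",
              linetype = "dashed") +
    geom_line(aes(y = .data$observed)) +
    geom_point(aes(y = .data$observed)) +
    labs(x = "Time after dose (h)",
         y = "Prediction-corrected concentration (mg/L)") +
    ggplot2::theme_bw()
}
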