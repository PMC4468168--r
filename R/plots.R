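# ggplot2 views of the three result types.

#' Plot group medians with bootstrap confidence intervals
#'
#' One panel per assay; points are group medians, bars the percentile
#' bootstrap intervals, colour distinguishes treatments.
#'
#' @param report A `"tolerance_report"` from [run_tolerance_analysis()].
#' @return A ggplot object.
#' @export
plot_tolerance_medians <- function(report) {
  stopifnot(inherits(report, "tolerance_report"))
  ggplot2::ggplot(report$medians,
                  ggplot2::aes(x = .data$sex, y = .data$median,
                               colour = .data$treatment)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper),
      position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::facet_wrap(~assay, scales = "free_y") +
    ggplot2::labs(y = "median score (min or °C)", x = NULL,
                  colour = "treatment") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.tolerance_report <- function(object, ...) {
  plot_tolerance_medians(object)
}

#' Plot standardized viability with fitted performance curves
#'
#' Vial-level standardized viabilities (points, jittered) with the
#' fitted standardized thermal performance curves per treatment.
#'
#' @param report A `"viability_report"` from [run_viability_analysis()].
#' @return A ggplot object.
#' @export
plot_viability_curves <- function(report) {
  stopifnot(inherits(report, "viability_report"))
  ggplot2::ggplot(report$standardized,
                  ggplot2::aes(x = .data$temperature,
                               y = .data$relative_viability,
                               colour = .data$treatment)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.35, size = 0.8) +
    ggplot2::geom_line(data = report$curve,
                       ggplot2::aes(y = .data$standardized_fitted),
                       linewidth = 0.9) +
    ggplot2::labs(x = "developmental temperature (°C)",
                  y = "viability relative to benign-temperature mean",
                  colour = "treatment") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.viability_report <- function(object, ...) {
  plot_viability_curves(object)
}

#' Plot a microhabitat temperature log
#'
#' @param log Tibble with columns `timestamp`, `sensor`, `temp_c`.
#' @return A ggplot object.
#' @export
plot_temperature_log <- function(log) {
  ggplot2::ggplot(log, ggplot2::aes(x = .data$timestamp, y = .data$temp_c,
                                    colour = .data$sensor)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = NULL, y = "temperature (°C)", colour = "sensor") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
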