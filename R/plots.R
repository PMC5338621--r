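#' Box-plot figure of an impedance sweep
#'
#' Median / interquartile box and min-max whiskers of RDM and MAG per
#' impedance, log-scaled impedance axis — the standard summary figure of the
#' model-comparison sweep.
#'
#' @param object a `cem_sweep` tibble from [run_comparison_sweep()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cem_sweep <- function(object, ...) {
  sm <- summarize_comparisons(object, by = "impedance")
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$impedance)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$min, ymax = .data$max),
                            linewidth = 0.3, colour = "grey50") +
    ggplot2::geom_crossbar(ggplot2::aes(y = .data$median, ymin = .data$iqr_low,
                                        ymax = .data$iqr_high),
                           width = 0.15, fill = "grey85") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~measure, scales = "free_y",
                        labeller = ggplot2::as_labeller(toupper)) +
    ggplot2::labs(x = "average contact impedance (Ohm)", y = "%") +
    ggplot2::theme_minimal()
}

#' Box-plot figure of the eccentricity analysis
#'
#' @param object a `cem_eccentricity` tibble from
#'   [run_eccentricity_analysis()].
#' @param measures which measures to draw.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cem_eccentricity <- function(object,
                                      measures = c("rdm", "mag", "pd", "ad", "nd"),
                                      ...) {
  sm <- summarize_comparisons(object, by = "eccentricity")
  sm <- sm[sm$measure %in% measures, ]
  ggplot2::ggplot(sm, ggplot2::aes(x = factor(.data$eccentricity))) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$min, ymax = .data$max),
                            linewidth = 0.3, colour = "grey50") +
    ggplot2::geom_crossbar(ggplot2::aes(y = .data$median, ymin = .data$iqr_low,
                                        ymax = .data$iqr_high),
                           width = 0.5, fill = "grey85") +
    ggplot2::facet_wrap(~measure, scales = "free_y",
                        labeller = ggplot2::as_labeller(toupper)) +
    ggplot2::labs(x = "eccentricity (relative norm)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Electrode voltage patterns for the two test sources
#'
#' @param object a `cem_source_ab` result from [run_source_ab()].
#' @param ... unused.
#' @return a ggplot object (voltage in microvolts per electrode, one line per
#'   model/impedance combination, faceted by source).
#' @export
autoplot.cem_source_ab <- function(object, ...) {
  v <- dplyr::mutate(object$voltages, uV = 1e6 * .data$voltage)
  ggplot2::ggplot(v, ggplot2::aes(x = .data$electrode, y = .data$uV,
                                  colour = .data$combo)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(~source, ncol = 1L, scales = "free_y") +
    ggplot2::labs(x = "electrode", y = "voltage (µV)", colour = NULL) +
    ggplot2::theme_minimal()
}
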