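#' Forest plot of CPM adjusted odds ratios
#'
#' @param object A `vf_cpm` fit.
#' @param conf.level Confidence level for the intervals.
#' @param ... Unused.
#' @return A ggplot: one row per slope, aOR with Wald interval on a log scale.
#' @export
autoplot.vf_cpm <- function(object, conf.level = 0.95, ...) {
  td <- tidy(object, conf.level = conf.level)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$aOR,
                                   y = stats::reorder(.data$term,
                                                      .data$statistic))) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "adjusted odds ratio (log scale)", y = NULL,
                  title = "Cumulative probability model: slope odds ratios") +
    ggplot2::theme_minimal()
}

#' Staircase plot of a participant's session
#'
#' Shows the stimulus force trajectory of each block with yes/no responses
#' and catch trials marked at the bottom of the panel.
#'
#' @param trials Trial log from [simulate_sessions()].
#' @param id Participant id to plot.
#' @return A ggplot faceted by block.
#' @export
plot_staircase <- function(trials, id = trials$id[1]) {
  d <- trials[trials$id == id, ]
  d$force_plot <- ifelse(is.na(d$force_g), min(trials$force_g, na.rm = TRUE) / 2,
                         d$force_g)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$force_plot)) +
    ggplot2::geom_line(data = d[d$kind == "stimulus", ], colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$kind,
                                     colour = .data$response), size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~ paste0("block ", .data$block, " (",
                                 .data$direction, ")")) +
    ggplot2::labs(x = "trial", y = "force (g, log scale)",
                  title = paste("Method-of-limits session:", id)) +
    ggplot2::theme_minimal()
}

#' Group distributions of a scored variable
#'
#' Jittered per-participant values by diagnosis within age band, with group
#' medians, for a quick look at threshold / Az / c group differences.
#'
#' @param dataset Participant-level dataset (e.g. from [simulate_study()]).
#' @param var Name of the numeric column to plot.
#' @param log_y Use a log10 y-axis (natural for forces in grams).
#' @return A ggplot.
#' @export
plot_group_distributions <- function(dataset, var = "threshold_g",
                                     log_y = identical(var, "threshold_g")) {
  d <- dataset[!is.na(dataset[[var]]), ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$diagnosis,
                                       y = .data[[var]],
                                       colour = .data$diagnosis)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.4, colour = "black") +
    ggplot2::labs(x = NULL, y = var) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
  if ("band" %in% names(d)) p <- p + ggplot2::facet_wrap(~ .data$band)
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}
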