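#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_hline geom_point
#'   geom_ribbon geom_errorbar labs theme_minimal facet_wrap
#'   annotate scale_colour_brewer
NULL

#' Plot an ERP waveform
#'
#' Amplitude against time with stimulus onset and zero lines; negative is
#' plotted downward following ERP convention.
#'
#' @param object an [erp_waveform()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.erp_waveform <- function(object, ...) {
  df <- tibble(time = object$time_axis, amplitude = object$amplitude)
  ggplot(df, aes(x = .data$time, y = .data$amplitude)) +
    geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70",
                        linetype = "dashed") +
    geom_line() +
    ggplot2::scale_y_reverse() +
    labs(x = "time (ms)", y = "amplitude (µV, negative up)",
         title = object$condition_set,
         subtitle = if (!is.na(object$n_trials))
           sprintf("%d trials", object$n_trials) else NULL) +
    theme_minimal()
}

#' Plot a reliability table
#'
#' ICC against trial count per feature, with 95% confidence ribbons and the
#' fair/good/excellent band edges.
#'
#' @param table a tibble from [test_retest_table()] or
#'   [internal_consistency()].
#' @return A ggplot.
#' @export
plot_reliability <- function(table) {
  df <- dplyr::filter(table, .data$n_trials != "all", !is.na(.data$icc)) |>
    dplyr::mutate(n = as.numeric(.data$n_trials))
  ggplot(df, aes(x = .data$n, y = .data$icc)) +
    geom_hline(yintercept = c(0.4, 0.6, 0.75), colour = "grey80",
               linetype = "dotted") +
    geom_ribbon(aes(ymin = .data$ci_low, ymax = .data$ci_high),
                fill = "steelblue", alpha = 0.2) +
    geom_line(colour = "steelblue") + geom_point(colour = "steelblue") +
    facet_wrap(~ feature) +
    labs(x = "trials in individual average", y = "ICC(3,1)") +
    theme_minimal()
}

#' Plot a DTW alignment path
#'
#' The warping path over the cost-matrix lattice with the main diagonal;
#' the signed area between them, normalised, is the direction statistic.
#'
#' @param object a `dtw_result` from [dtw_align()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.dtw_result <- function(object, ...) {
  ggplot(object$path, aes(x = .data$i, y = .data$j)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70",
                         linetype = "dashed") +
    geom_line(colour = "steelblue") +
    labs(x = "reference index", y = "individual index",
         title = sprintf("DTW direction = %.3f", object$direction)) +
    theme_minimal()
}
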