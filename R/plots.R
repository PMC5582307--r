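# ggplot2 display methods.

#' @rdname autoplot_dusbeats
#' @name autoplot_dusbeats
#' @title Plot methods for dusbeats objects
#' @description `autoplot()` draws the natural display of each result type:
#'   waveform for a `dus_signal`, stacked components for an `imf_set`,
#'   interval tachogram for a `beat_series`, objective heat maps for a
#'   calibrated `selection_result`, and the waveform with true/detected beat
#'   markers for a `synthetic_record`.
#' @param object object to plot.
#' @param ... unused.
#' @return a ggplot.
NULL

#' @rdname autoplot_dusbeats
#' @export
autoplot.dus_signal <- function(object, ...) {
  ggplot2::ggplot(tidy.dus_signal(object),
                  ggplot2::aes(.data$time_ms / 1000, .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (s)", y = "amplitude", title = object$label) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot_dusbeats
#' @export
autoplot.imf_set <- function(object, ...) {
  tb <- tidy.imf_set(object)
  tb$component <- factor(tb$component, levels = unique(tb$component))
  ggplot2::ggplot(tb, ggplot2::aes(.data$time_ms / 1000, .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$component), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot_dusbeats
#' @export
autoplot.beat_series <- function(object, ...) {
  tb <- tidy.beat_series(object)
  ggplot2::ggplot(tb[-1, ], ggplot2::aes(.data$beat_time_ms / 1000, .data$interval_ms)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (s)", y = "beat-to-beat interval (ms)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot_dusbeats
#' @export
autoplot.selection_result <- function(object, ...) {
  if (is.null(object$surface)) {
    rlang::abort("default-mode selections have no surface to plot",
                 class = "dusbeats_bad_args")
  }
  tb <- tidyr::pivot_longer(
    object$surface, c("abs_mismatch_pct", "var_b_loc_ms"),
    names_to = "objective", values_to = "value"
  )
  tb$value[!is.finite(tb$value)] <- NA
  ggplot2::ggplot(tb, ggplot2::aes(.data$window_ms, factor(.data$imf_index),
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(ggplot2::vars(.data$objective), scales = "free") +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::labs(x = "kurtosis window (ms)", y = "IMF level", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot_dusbeats
#' @export
autoplot.synthetic_record <- function(object, ...) {
  tb <- tidy.dus_signal(object$dus)
  beats <- tibble::tibble(beat_time_ms = beat_times(object$true_beats))
  ggplot2::ggplot(tb, ggplot2::aes(.data$time_ms / 1000, .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.2, colour = "grey30") +
    ggplot2::geom_vline(data = beats,
                        ggplot2::aes(xintercept = .data$beat_time_ms / 1000),
                        colour = "red", alpha = 0.4, linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "amplitude",
                  title = "synthetic DUS with true beat times") +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot of paired true/estimated measures
#'
#' @param true_vals,est_vals paired measurements, equal length >= 2.
#' @param label axis label for the measure.
#' @return a ggplot with the mean difference and the mean +/- 2 SD limits.
#' @export
plot_bland_altman <- function(true_vals, est_vals, label = "measure") {
  ba <- bland_altman(true_vals, est_vals)
  tb <- tibble::tibble(
    avg = (as.numeric(true_vals) + as.numeric(est_vals)) / 2,
    diff = as.numeric(true_vals) - as.numeric(est_vals)
  )
  ggplot2::ggplot(tb, ggplot2::aes(.data$avg, .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = ba$mean_diff, linetype = 1) +
    ggplot2::geom_hline(yintercept = c(ba$lower_limit, ba$upper_limit),
                        linetype = 2) +
    ggplot2::labs(x = sprintf("mean of true and estimated %s", label),
                  y = sprintf("true - estimated %s", label)) +
    ggplot2::theme_minimal()
}
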