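# broom-style tidiers: every container converts to a long tibble with
# tidy(), fitted-result objects summarise to one row with glance().

#' @rdname tidy_dusbeats
#' @name tidy_dusbeats
#' @title Tidy methods for dusbeats objects
#' @description Convert dusbeats containers to tibbles: a `dus_signal`
#'   becomes `(time_ms, amplitude)`, an `imf_set` becomes long
#'   `(time_ms, component, value)`, a `kurtosis_matrix` becomes long
#'   `(imf_index, window_ms, time_ms, kurtosis)`, a `beat_series` gains the
#'   interval column, a `selection_result` returns its objective surface and
#'   an `evaluation_report` its per-metric values.
#' @param x object to tidy.
#' @param ... unused.
#' @return a tibble.
NULL

#' @rdname tidy_dusbeats
#' @export
tidy.dus_signal <- function(x, ...) {
  tibble::tibble(
    time_ms = samples_to_ms(seq_along(x$samples) - 1, x$fs),
    amplitude = x$samples
  )
}

#' @rdname tidy_dusbeats
#' @export
tidy.imf_set <- function(x, ...) {
  t_ms <- samples_to_ms(seq_len(x$source_length) - 1, x$fs)
  comps <- c(
    if (x$n_imfs > 0) {
      purrr::map(seq_len(x$n_imfs), function(i) {
        tibble::tibble(time_ms = t_ms, component = paste0("imf_", i),
                       value = x$imfs[, i])
      })
    },
    list(tibble::tibble(time_ms = t_ms, component = "residue", value = x$residue))
  )
  dplyr::bind_rows(comps)
}

#' @rdname tidy_dusbeats
#' @export
tidy.kurtosis_vector <- function(x, ...) {
  tibble::tibble(
    imf_index = x$imf_index,
    window_ms = x$window_ms,
    time_ms = samples_to_ms(seq_along(x$values) - 1 + floor(x$n_window_samples / 2), x$fs),
    kurtosis = x$values
  )
}

#' @rdname tidy_dusbeats
#' @export
tidy.kurtosis_matrix <- function(x, ...) {
  dplyr::bind_rows(purrr::map(x$kv, tidy.kurtosis_vector))
}

#' @rdname tidy_dusbeats
#' @export
tidy.beat_series <- function(x, ...) {
  t <- beat_times(x)
  tibble::tibble(
    beat = seq_along(t),
    beat_time_ms = t,
    interval_ms = c(NA_real_, diff(t))
  )
}

#' @rdname tidy_dusbeats
#' @export
tidy.selection_result <- function(x, ...) {
  if (is.null(x$surface)) {
    dplyr::mutate(x$selected, selected = TRUE, .before = 1)
  } else {
    dplyr::mutate(
      x$surface,
      selected = paste(.data$imf_index, .data$window_ms) %in%
        paste(x$selected$imf_index, x$selected$window_ms)
    )
  }
}

#' @rdname tidy_dusbeats
#' @export
tidy.evaluation_report <- function(x, ...) {
  tibble::tibble(
    metric = c("mismatch_pct", "mean_successive_beat_error_pct",
               "sbe_aligned_pct", "var_b_loc_ms"),
    value = c(x$mismatch_pct, x$mean_successive_beat_error_pct,
              x$sbe_aligned_pct, x$var_b_loc_ms)
  )
}

#' One-row summary of an evaluation report
#' @param x an `evaluation_report`.
#' @param ... unused.
#' @return a one-row tibble with the error metrics and both HRV summaries
#'   (`*_true` / `*_est` suffixes).
#' @export
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(
    mismatch_pct = x$mismatch_pct,
    sbe_pct = x$mean_successive_beat_error_pct,
    sbe_aligned_pct = x$sbe_aligned_pct,
    var_b_loc_ms = x$var_b_loc_ms,
    n_true = x$n_true,
    n_est = x$n_est,
    mean_bb_true = x$hrv_true$mean_bb,
    sdnn_true = x$hrv_true$sdnn,
    rmssd_true = x$hrv_true$rmssd,
    mean_bb_est = x$hrv_est$mean_bb,
    sdnn_est = x$hrv_est$sdnn,
    rmssd_est = x$hrv_est$rmssd
  )
}
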