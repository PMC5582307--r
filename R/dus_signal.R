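#' Uniformly sampled waveform
#'
#' Light container for a single-channel Doppler ultrasound (or any sampled)
#' waveform: a numeric sample vector plus its sampling rate. Clinical fetal
#' DUS is typically acquired at 1 kHz with 16-bit resolution; the synthetic
#' generator and the readers produce signals in this form.
#'
#' @param samples numeric vector of amplitudes; must be finite, length >= 2.
#' @param fs sampling rate in Hz (> 0).
#' @param label free-text tag carried through processing stages.
#'
#' @return An object of class `dus_signal`: a list with elements `samples`,
#'   `fs` and `label`.
#' @examples
#' s <- dus_signal(sin(2 * pi * 10 * seq(0, 1, by = 1e-3)), fs = 1000)
#' duration_ms(s)
#' @export
dus_signal <- function(samples, fs, label = "") {
  stopifnot_finite(samples, "samples")
  if (length(samples) < 2) {
    rlang::abort("a dus_signal needs at least 2 samples", class = "dusbeats_bad_signal")
  }
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    rlang::abort("fs must be a single positive number (Hz)", class = "dusbeats_bad_signal")
  }
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs), label = as.character(label)),
    class = "dus_signal"
  )
}

#' @export
print.dus_signal <- function(x, ...) {
  cat(sprintf(
    "<dus_signal> %d samples @ %g Hz (%.1f s)%s\n",
    length(x$samples), x$fs, length(x$samples) / x$fs,
    if (nzchar(x$label)) paste0(" [", x$label, "]") else ""
  ))
  invisible(x)
}

#' @export
length.dus_signal <- function(x) length(x$samples)

#' Signal duration in milliseconds
#' @param x a `dus_signal`.
#' @return duration in ms.
#' @export
duration_ms <- function(x) {
  stopifnot(inherits(x, "dus_signal"))
  samples_to_ms(length(x$samples), x$fs)
}

as_signal_samples <- function(x) {
  if (inherits(x, "dus_signal")) x$samples else as.numeric(x)
}

signal_fs <- function(x, fs = NULL) {
  if (inherits(x, "dus_signal")) x$fs else fs %||%
    rlang::abort("fs must be supplied for a bare numeric signal")
}

#' Strictly increasing beat-time series
#'
#' Beat series carry detected (or ground-truth) beat times in milliseconds as
#' a tibble with a single column `beat_time_ms`; successive differences are
#' the beat-to-beat intervals used by every evaluation metric.
#'
#' @param beat_time_ms numeric vector of beat times (ms), strictly increasing,
#'   all non-negative.
#' @return A tibble of class `beat_series` with column `beat_time_ms`.
#' @examples
#' b <- beat_series(c(400, 810, 1205))
#' beat_intervals(b)
#' @export
beat_series <- function(beat_time_ms) {
  beat_time_ms <- as.numeric(beat_time_ms)
  stopifnot_finite(beat_time_ms, "beat times")
  if (length(beat_time_ms) == 0) {
    rlang::abort("beat series must contain at least one beat", class = "dusbeats_empty_beats")
  }
  if (any(beat_time_ms < 0)) {
    rlang::abort("beat times must be non-negative", class = "dusbeats_bad_beats")
  }
  if (length(beat_time_ms) > 1 && any(diff(beat_time_ms) <= 0)) {
    bad <- which(diff(beat_time_ms) <= 0)[1] + 1
    rlang::abort(
      sprintf("beat times must be strictly increasing (row %d violates this)", bad),
      class = "dusbeats_bad_beats"
    )
  }
  out <- tibble::tibble(beat_time_ms = beat_time_ms)
  class(out) <- c("beat_series", class(out))
  out
}

#' Beat-to-beat intervals of a beat series
#' @param beats a `beat_series` (or anything coercible via its
#'   `beat_time_ms` column).
#' @return numeric vector of successive differences (ms); length
#'   `nrow(beats) - 1`.
#' @export
beat_intervals <- function(beats) {
  diff(beat_times(beats))
}

beat_times <- function(beats) {
  if (inherits(beats, "beat_series") || (is.data.frame(beats) && "beat_time_ms" %in% names(beats))) {
    return(as.numeric(beats$beat_time_ms))
  }
  as.numeric(beats)
}
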