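# Readers and writers for the two on-disk signal dialects (16-bit PCM WAV and
# a two-column CSV) and for beat-annotation CSVs.
#
# The WAV code handles exactly the flavour the acquisition hardware in this
# domain produces -- mono, uncompressed PCM, 16 bits -- so it is written
# directly against the RIFF layout rather than pulling in an audio stack.

#' Read a sampled signal from WAV or CSV
#'
#' WAV input must be mono 16-bit PCM; samples are rescaled to \[-1, 1\] and
#' the sampling rate is taken from the header. CSV input follows the dialect
#' written by [write_signal()]: header `time_ms,amplitude`, one sample per
#' row; the sampling rate is inferred from the time column, which must be
#' uniform and strictly increasing.
#'
#' @param path file to read.
#' @param format `"auto"` (by extension), `"wav"` or `"csv"`.
#' @return a [dus_signal()].
#' @export
read_signal <- function(path, format = c("auto", "wav", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    rlang::abort(sprintf("file not found: %s", path), class = "dusbeats_io")
  }
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      wav = "wav", csv = "csv",
      rlang::abort(sprintf("cannot infer format from extension of '%s'", path),
                   class = "dusbeats_io")
    )
  }
  if (format == "wav") read_wav_pcm16(path) else read_signal_csv(path)
}

#' Write a sampled signal to WAV or CSV
#'
#' @param x a [dus_signal()].
#' @param path output file.
#' @param format `"auto"` (by extension), `"wav"` (16-bit PCM; amplitudes are
#'   clipped to \[-1, 1\] and quantised) or `"csv"` (`time_ms,amplitude`).
#' @return `path`, invisibly.
#' @export
write_signal <- function(x, path, format = c("auto", "wav", "csv")) {
  stopifnot(inherits(x, "dus_signal"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      wav = "wav", csv = "csv",
      rlang::abort(sprintf("cannot infer format from extension of '%s'", path),
                   class = "dusbeats_io")
    )
  }
  if (format == "wav") {
    write_wav_pcm16(x, path)
  } else {
    tb <- tibble::tibble(
      time_ms = samples_to_ms(seq_along(x$samples) - 1, x$fs),
      amplitude = x$samples
    )
    readr::write_csv(tb, path, progress = FALSE)
  }
  invisible(path)
}

read_signal_csv <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("time_ms", "amplitude") %in% names(tb))) {
    rlang::abort("signal CSV must have columns time_ms,amplitude", class = "dusbeats_io")
  }
  if (nrow(tb) < 2) {
    rlang::abort("signal CSV has fewer than 2 rows", class = "dusbeats_io")
  }
  dt <- diff(tb$time_ms)
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1] + 1
    rlang::abort(sprintf("time column not strictly increasing at row %d", bad + 1),
                 class = "dusbeats_io")
  }
  step <- stats::median(dt)
  if (any(abs(dt - step) > 0.01 * step)) {
    bad <- which(abs(dt - step) > 0.01 * step)[1] + 1
    rlang::abort(sprintf("non-uniform sampling near row %d", bad + 1),
                 class = "dusbeats_io")
  }
  dus_signal(tb$amplitude, fs = 1000 / step, label = basename(path))
}

read_wav_pcm16 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    rlang::abort(sprintf("'%s': not a RIFF file (byte 0)", path), class = "dusbeats_io")
  }
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    rlang::abort(sprintf("'%s': RIFF form is not WAVE (byte 8)", path), class = "dusbeats_io")
  }
  fs <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      channels <- fmt[2]
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little")) # byte rate
      invisible(readBin(con, "integer", 1, size = 2, endian = "little")) # block align
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (fmt[1] != 1L) {
        rlang::abort("only uncompressed PCM WAV is supported", class = "dusbeats_io")
      }
      if (sz > 16) invisible(readBin(con, "raw", sz - 16))
    } else if (id == "data") {
      if (is.null(bits)) rlang::abort("WAV data chunk before fmt chunk", class = "dusbeats_io")
      samples <- readBin(con, "integer", sz / 2, size = 2, signed = TRUE, endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", sz + (sz %% 2)))
    }
  }
  if (is.null(fs) || is.null(samples)) {
    rlang::abort(sprintf("'%s': missing fmt or data chunk", path), class = "dusbeats_io")
  }
  if (bits != 16L || channels != 1L) {
    rlang::abort("only mono 16-bit WAV is supported", class = "dusbeats_io")
  }
  dus_signal(samples / 32767, fs = fs, label = basename(path))
}

write_wav_pcm16 <- function(x, path) {
  pcm <- as.integer(round(pmax(pmin(x$samples, 1), -1) * 32767))
  fs <- as.integer(round(x$fs))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read beat annotations
#'
#' Beat CSVs have a single header `beat_time_ms` and one strictly increasing
#' time (ms) per row. Round-trips through [write_beats()] are lossless.
#'
#' @param path CSV file of beat times.
#' @return a [beat_series()].
#' @export
read_beats <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("file not found: %s", path), class = "dusbeats_io")
  }
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"beat_time_ms" %in% names(tb)) {
    rlang::abort("beat CSV must have header beat_time_ms", class = "dusbeats_io")
  }
  if (nrow(tb) == 0) {
    rlang::abort(sprintf("'%s' contains no beats", path), class = "dusbeats_io")
  }
  t <- tb$beat_time_ms
  if (length(t) > 1 && any(diff(t) <= 0)) {
    bad <- which(diff(t) <= 0)[1] + 1
    rlang::abort(sprintf("beat times not strictly increasing at row %d of '%s'", bad + 1, path),
                 class = "dusbeats_io")
  }
  beat_series(t)
}

#' Write beat annotations
#' @param beats a [beat_series()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_beats <- function(beats, path) {
  t <- beat_times(beats)
  readr::write_csv(tibble::tibble(beat_time_ms = t), path, progress = FALSE)
  invisible(path)
}
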