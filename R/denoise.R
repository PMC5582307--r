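# Multilevel Haar wavelet denoising.
#
# The Haar analysis/synthesis pair is a two-tap orthonormal filter bank, so
# the transform is written directly: a = (x1 + x2)/sqrt(2), d = (x1 - x2)/
# sqrt(2) per pair, recursed on the approximation. Odd-length levels are
# extended symmetrically by one sample (repeating the last value) and the
# padding is dropped on reconstruction, which avoids the edge bursts a
# periodic extension would create -- spurious edge transients would later
# masquerade as kurtosis peaks.

haar_decompose <- function(x, levels) {
  details <- vector("list", levels)
  lengths <- integer(levels)
  a <- x
  for (l in seq_len(levels)) {
    lengths[l] <- length(a)
    if (length(a) %% 2 == 1) a <- c(a, a[length(a)])
    odd <- a[seq(1, length(a), by = 2)]
    even <- a[seq(2, length(a), by = 2)]
    details[[l]] <- (odd - even) / sqrt(2)
    a <- (odd + even) / sqrt(2)
  }
  list(approx = a, details = details, lengths = lengths)
}

haar_reconstruct <- function(dec) {
  a <- dec$approx
  for (l in rev(seq_along(dec$details))) {
    d <- dec$details[[l]]
    out <- numeric(2 * length(d))
    out[seq(1, length(out), by = 2)] <- (a + d) / sqrt(2)
    out[seq(2, length(out), by = 2)] <- (a - d) / sqrt(2)
    a <- out[seq_len(dec$lengths[l])]
  }
  a
}

#' Wavelet denoising of a raw DUS signal
#'
#' Decomposes the signal to `levels` levels with the Haar basis, soft-
#' thresholds every detail level, and reconstructs. Each level gets the
#' universal threshold `sigma * sqrt(2 * log(N_level))`, where `N_level` is
#' that level's coefficient count and the noise scale `sigma` is estimated
#' robustly from the finest detail level as `median(|d1|) / 0.6745`.
#' Broadband background noise spreads evenly over all detail levels while
#' burst energy concentrates in the coarser ones, so the per-level threshold
#' removes noise aggressively at fine scales and spares the (shorter) coarse
#' levels where the cardiac content lives.
#'
#' If the signal is shorter than `2^levels` samples the depth is reduced to
#' the maximum feasible level, with a warning.
#'
#' @param x a [dus_signal()] (or numeric vector with `fs`).
#' @param levels decomposition depth; default 15.
#' @param fs sampling rate, only needed when `x` is a bare numeric vector.
#' @return a denoised [dus_signal()] of identical length and sampling rate.
#' @examples
#' rec <- synthesize_dus(generate_rr_sequence(400, 0, 0, 20, seed = 1),
#'                       snr_db = 10, seed = 1)
#' den <- denoise_wavelet(rec$dus)
#' @export
denoise_wavelet <- function(x, levels = 15, fs = NULL) {
  samples <- as_signal_samples(x)
  fs <- signal_fs(x, fs)
  stopifnot_finite(samples, "signal")
  n <- length(samples)
  max_levels <- floor(log2(n))
  if (levels > max_levels) {
    rlang::warn(sprintf(
      "signal of length %d supports at most %d Haar levels; reducing from %d",
      n, max_levels, levels
    ), class = "dusbeats_levels_reduced")
    levels <- max_levels
  }
  dec <- haar_decompose(samples, levels)
  sigma <- stats::median(abs(dec$details[[1]])) / 0.6745
  dec$details <- lapply(dec$details, function(d) {
    thr <- sigma * sqrt(2 * log(length(d)))
    sign(d) * pmax(abs(d) - thr, 0)
  })
  out <- haar_reconstruct(dec)
  dus_signal(out, fs = fs,
             label = if (inherits(x, "dus_signal") && nzchar(x$label)) {
               paste0(x$label, " (denoised)")
             } else "denoised")
}
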