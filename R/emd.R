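#' Intrinsic mode function set
#'
#' Container for the output of [emd()] / [eemd()]: the ordered intrinsic mode
#' functions (IMFs) and the final residue. For plain EMD the construction is
#' telescoping, so the IMFs plus residue reconstruct the input to numerical
#' precision; for EEMD the averaged modes reconstruct the input only up to
#' the averaged ensemble noise.
#'
#' @param imfs numeric matrix, one IMF per column (possibly zero columns).
#' @param residue numeric vector, same length as the IMFs.
#' @param fs sampling rate of the source signal (Hz).
#' @return an object of class `imf_set` with elements `imfs`, `residue`,
#'   `fs`, `n_imfs` and `source_length`.
#' @export
imf_set <- function(imfs, residue, fs) {
  imfs <- as.matrix(imfs)
  if (nrow(imfs) > 0 && nrow(imfs) != length(residue)) {
    rlang::abort("imfs and residue must have equal length", class = "dusbeats_bad_imfset")
  }
  structure(
    list(imfs = imfs, residue = as.numeric(residue), fs = fs,
         n_imfs = ncol(imfs), source_length = length(residue)),
    class = "imf_set"
  )
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMFs + residue, %d samples @ %g Hz\n",
              x$n_imfs, x$source_length, x$fs))
  invisible(x)
}

#' Extract one intrinsic mode function by sifting
#'
#' One round of the sifting procedure: the mean of the cubic-spline upper and
#' lower extremal envelopes is subtracted repeatedly until the standard SD
#' stopping criterion `sum((h_prev - h_new)^2) / sum(h_prev^2) < sd_tol` is
#' met or `max_sift_iters` is reached. Envelopes use natural cubic splines
#' through the extrema, with the two outermost extrema on each side mirrored
#' beyond the signal ends to suppress endpoint swings. The result satisfies
#' the IMF condition: extrema and zero-crossing counts differ by at most one.
#'
#' @param x numeric vector with at least 4 extrema.
#' @param max_sift_iters maximum sifting iterations (default 100).
#' @param sd_tol stopping tolerance (default 0.05).
#' @return numeric vector: the IMF candidate.
#' @section Errors: a signal with fewer than 4 extrema (e.g. a monotone ramp)
#'   raises a condition of class `dusbeats_monotone_residue`; [emd()] uses
#'   this to stop decomposition.
#' @export
emd_sift <- function(x, max_sift_iters = 100, sd_tol = 0.05) {
  stopifnot_finite(x, "signal")
  res <- .sift_cpp(as.numeric(x), as.integer(max_sift_iters), sd_tol)
  if (isTRUE(res$monotone)) {
    rlang::abort("monotone residue: fewer than 4 extrema, nothing left to sift",
                 class = "dusbeats_monotone_residue")
  }
  res$imf
}

#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions by repeated sifting on
#' successive residues, stopping at `max_imfs` modes or when the residue has
#' fewer than 4 extrema. The decomposition telescopes, so
#' `rowSums(imfs) + residue` equals the input to numerical precision.
#'
#' @param x a [dus_signal()] or numeric vector.
#' @param max_imfs maximum number of modes (default 10; at 1 kHz the beat-
#'   scale structure lives in the first few modes).
#' @param max_sift_iters,sd_tol sifting controls, see [emd_sift()].
#' @param fs sampling rate when `x` is a bare vector.
#' @return an [imf_set()].
#' @examples
#' t <- seq(0, 2, by = 1e-3)
#' x <- sin(2 * pi * 50 * t) + sin(2 * pi * 2 * t)
#' dec <- emd(x, fs = 1000)
#' dec$n_imfs
#' @export
emd <- function(x, max_imfs = 10, max_sift_iters = 100, sd_tol = 0.05, fs = NULL) {
  samples <- as_signal_samples(x)
  fs <- if (inherits(x, "dus_signal")) x$fs else (fs %||% NA_real_)
  stopifnot_finite(samples, "signal")
  res <- .emd_cpp(samples, as.integer(max_imfs), as.integer(max_sift_iters), sd_tol)
  imf_set(res$imfs, res$residue, fs = fs)
}

#' Ensemble empirical mode decomposition
#'
#' Averages aligned IMFs over `ensemble_size` EMD runs of the signal plus
#' white noise of standard deviation `noise_sd_fraction * sd(x)`. The added
#' noise populates the whole time-frequency plane so that intermittent
#' components no longer hop between modes (the mode-mixing problem of plain
#' EMD); averaging cancels the noise at rate `1/sqrt(ensemble_size)`. The
#' mode count is fixed across members at the ensemble minimum; any extra
#' modes of a member are folded into its residue before averaging, so the
#' average of the member reconstructions is preserved.
#'
#' With `ensemble_size = 1` and `noise_sd_fraction = 0` the result is
#' identical to [emd()].
#'
#' @inheritParams emd
#' @param ensemble_size number of noise realisations (>= 1; default 100).
#' @param noise_sd_fraction noise SD as a fraction of `sd(x)` (default 0.2).
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return an [imf_set()].
#' @export
eemd <- function(x, ensemble_size = 100, noise_sd_fraction = 0.2, seed = 1,
                 max_imfs = 10, max_sift_iters = 100, sd_tol = 0.05, fs = NULL) {
  samples <- as_signal_samples(x)
  fs <- if (inherits(x, "dus_signal")) x$fs else (fs %||% NA_real_)
  stopifnot_finite(samples, "signal")
  if (ensemble_size < 1) {
    rlang::abort("ensemble_size must be >= 1", class = "dusbeats_bad_args")
  }
  if (noise_sd_fraction < 0) {
    rlang::abort("noise_sd_fraction must be >= 0", class = "dusbeats_bad_args")
  }
  if (ensemble_size == 1 && noise_sd_fraction == 0) {
    return(emd(samples, max_imfs = max_imfs, max_sift_iters = max_sift_iters,
               sd_tol = sd_tol, fs = fs))
  }
  n <- length(samples)
  noise_sd <- noise_sd_fraction * stats::sd(samples)
  runs <- with_seed_(seed, {
    lapply(seq_len(ensemble_size), function(e) {
      noise <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
      .emd_cpp(samples + noise, as.integer(max_imfs),
               as.integer(max_sift_iters), sd_tol)
    })
  })
  n_modes <- min(vapply(runs, function(r) ncol(r$imfs), integer(1)))
  if (n_modes == 0) {
    residue <- Reduce(`+`, lapply(runs, `[[`, "residue")) / ensemble_size
    return(imf_set(matrix(numeric(0), nrow = n, ncol = 0), residue, fs = fs))
  }
  imfs <- matrix(0, nrow = n, ncol = n_modes)
  residue <- numeric(n)
  for (r in runs) {
    imfs <- imfs + r$imfs[, seq_len(n_modes), drop = FALSE]
    extra <- if (ncol(r$imfs) > n_modes) {
      rowSums(r$imfs[, -seq_len(n_modes), drop = FALSE])
    } else 0
    residue <- residue + r$residue + extra
  }
  imf_set(imfs / ensemble_size, residue / ensemble_size, fs = fs)
}

#' Count extrema and zero crossings of a vector
#'
#' Helper for checking the IMF condition (counts must agree to within one).
#'
#' @param x numeric vector.
#' @param edge_margin fraction of the signal excluded at each end (default 0,
#'   i.e. the whole vector).
#' @return a list with `n_extrema` and `n_zero_crossings`.
#' @export
count_extrema_zc <- function(x, edge_margin = 0) {
  x <- as.numeric(x)
  n <- length(x)
  if (edge_margin > 0) {
    keep <- seq.int(max(1, floor(n * edge_margin)), min(n, ceiling(n * (1 - edge_margin))))
    x <- x[keep]
  }
  ext <- .extrema_cpp(x)
  s <- sign(x)
  s <- s[s != 0]
  list(
    n_extrema = length(ext$maxima) + length(ext$minima),
    n_zero_crossings = sum(diff(s) != 0)
  )
}

#' Serialize an IMF set to CSV
#'
#' Writes columns `imf_1..imf_N` and `residue`, one sample per row.
#' @param x an [imf_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_imf_set <- function(x, path) {
  stopifnot(inherits(x, "imf_set"))
  tb <- tibble::as_tibble(as.data.frame(x$imfs, optional = TRUE),
                          .name_repair = "minimal")
  names(tb) <- if (x$n_imfs > 0) paste0("imf_", seq_len(x$n_imfs)) else character(0)
  tb$residue <- x$residue
  readr::write_csv(tb, path, progress = FALSE)
  invisible(path)
}
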