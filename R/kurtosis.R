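#' Non-centered kurtosis ratio of a signal window
#'
#' The impulsiveness statistic at the heart of the detector:
#' `(N - 1) * sum(x^4) / (sum(x^2))^2`. This is *not* the mean-centered
#' excess kurtosis; it is a normalized fourth-moment ratio that is large when
#' the window's energy is concentrated in a few samples (a Doppler burst) and
#' close to 3 for Gaussian noise. An all-zero window is defined as 0 so that
#' silent segments never rank as peaks.
#'
#' @param x numeric vector, length >= 2.
#' @return the kurtosis ratio (>= 0).
#' @examples
#' kurtosis_ratio(rep(2, 10))              # (N-1)/N = 0.9
#' kurtosis_ratio(c(1, numeric(9)))        # N-1 = 9
#' @export
kurtosis_ratio <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2) {
    rlang::abort("kurtosis_ratio needs at least 2 samples", class = "dusbeats_bad_args")
  }
  s2 <- sum(x^2)
  if (s2 == 0) return(0)
  (length(x) - 1) * sum(x^4) / s2^2
}

#' Kurtosis vector constructor
#'
#' A kurtosis vector holds the sliding-window kurtosis of one IMF at one
#' window size, one value per shift. Values are time-stamped at the window
#' *center*: value `k` (1-based, shift of `k - 1` samples) corresponds to
#' time `(k - 1 + W/2) / fs * 1000` ms, aligning kurtosis peaks with burst
#' centers.
#'
#' @param values numeric vector of kurtosis values (all >= 0).
#' @param window_ms window width in ms.
#' @param fs sampling rate (Hz).
#' @param imf_index index of the source IMF (or `NA`).
#' @param n_window_samples window width in samples.
#' @return an object of class `kurtosis_vector`.
#' @export
kurtosis_vector <- function(values, window_ms, fs, imf_index = NA_integer_,
                            n_window_samples = ms_to_samples(window_ms, fs)) {
  structure(
    list(values = as.numeric(values), window_ms = window_ms, fs = fs,
         imf_index = imf_index, n_window_samples = as.integer(n_window_samples)),
    class = "kurtosis_vector"
  )
}

#' @export
print.kurtosis_vector <- function(x, ...) {
  cat(sprintf("<kurtosis_vector> IMF %s, window %g ms (%d samples), %d values\n",
              format(x$imf_index), x$window_ms, x$n_window_samples, length(x$values)))
  invisible(x)
}

#' Sliding-window kurtosis of an IMF
#'
#' Computes [kurtosis_ratio()] over every window position of width
#' `window_ms`, advanced by `shift_ms` (1 ms by default, i.e. one sample at
#' 1 kHz). The running second and fourth power sums are accumulated once, so
#' the whole vector costs O(n) rather than O(n * W).
#'
#' @param imf numeric vector (one IMF).
#' @param fs sampling rate (Hz).
#' @param window_ms window width (ms); must not exceed the signal duration.
#' @param shift_ms shift between window starts (ms), default 1.
#' @param imf_index carried into the result for bookkeeping.
#' @return a [kurtosis_vector()] with `floor((n - W) / shift) + 1` values.
#' @export
sliding_kurtosis <- function(imf, fs, window_ms, shift_ms = 1, imf_index = NA_integer_) {
  imf <- as.numeric(imf)
  n <- length(imf)
  w <- ms_to_samples(window_ms, fs)
  if (w < 2) {
    rlang::abort("window too short: fewer than 2 samples", class = "dusbeats_bad_args")
  }
  if (w > n) {
    rlang::abort(sprintf("window (%d samples) longer than signal (%d samples)", w, n),
                 class = "dusbeats_bad_args")
  }
  shift <- max(1L, ms_to_samples(shift_ms, fs))
  c2 <- c(0, cumsum(imf^2))
  c4 <- c(0, cumsum(imf^4))
  starts <- seq.int(1L, n - w + 1L, by = shift)
  s2 <- pmax(c2[starts + w] - c2[starts], 0)
  s4 <- pmax(c4[starts + w] - c4[starts], 0)
  vals <- ifelse(s2 > 0, (w - 1) * s4 / s2^2, 0)
  kurtosis_vector(vals, window_ms = window_ms, fs = fs,
                  imf_index = imf_index, n_window_samples = w)
}

#' Chebyshev-style screen for heavy-tailed (informative) vectors
#'
#' Decides whether a vector carries genuine heavy-tailed excursions
#' (burst-scale peaks) rather than noise-like spread. The vector passes when
#' the fraction of samples farther than `lambda_sd` standard deviations from
#' the mean exceeds `selectivity / lambda_sd^2`, a `selectivity`-scaled share
#' of the Chebyshev bound `1 / lambda_sd^2`. At the default `lambda_sd = 3.5`
#' the cap is ~0.8%: white Gaussian noise stays far below it (its 3.5 SD tail
#' mass is ~0.05%) and fails, a constant vector fails (zero variance), while
#' a vector spending even ~1% of its samples in large excursions passes.
#' Burst-carrying IMFs are amplitude-sparse in exactly this sense.
#'
#' @param candidate finite numeric vector, length >= 2.
#' @param lambda_sd excursion threshold in SD units (default 3.5).
#' @param selectivity fraction of the Chebyshev bound that the tail mass must
#'   exceed (default 0.1).
#' @return `TRUE` if the vector looks heavy-tailed, else `FALSE`.
#' @export
chebyshev_screen <- function(candidate, lambda_sd = 3.5, selectivity = 0.1) {
  candidate <- as.numeric(candidate)
  stopifnot_finite(candidate, "candidate")
  if (length(candidate) < 2) {
    rlang::abort("candidate must have length >= 2", class = "dusbeats_bad_args")
  }
  s <- stats::sd(candidate)
  if (s == 0) return(FALSE)
  z <- abs(candidate - mean(candidate)) / s
  mean(z >= lambda_sd) > selectivity / lambda_sd^2
}

#' Build the (IMF x window) sliding-kurtosis matrix
#'
#' Screens each IMF with [chebyshev_screen()] applied to its amplitude
#' vector (burst-carrying modes are amplitude-sparse and heavy-tailed; noise
#' modes are not), then computes one kurtosis vector per surviving IMF and
#' window size on the default 50-600 ms grid (step 50 ms, i.e. 12 windows).
#' Three surviving IMFs on the default grid give a 36-cell matrix.
#'
#' @param imfs an [imf_set()] (or numeric matrix of IMFs in columns).
#' @param fs sampling rate; taken from the `imf_set` when available.
#' @param windows window grid in ms (default `seq(50, 600, by = 50)`).
#' @param shift_ms shift between window starts (ms), default 1.
#' @param screen apply the Chebyshev screen (default `TRUE`); with `FALSE`
#'   every IMF enters the matrix.
#' @param lambda_sd,selectivity screen parameters, see [chebyshev_screen()].
#' @param max_imf_levels cap on the number of IMF levels considered (default
#'   all).
#' @return a `kurtosis_matrix`: a tibble with one row per (IMF, window) cell,
#'   columns `imf_index`, `window_ms`, `n_window_samples` and a list-column
#'   `kv` of [kurtosis_vector()]s.
#' @export
build_kurtosis_matrix <- function(imfs, fs = NULL,
                                  windows = seq(50, 600, by = 50),
                                  shift_ms = 1, screen = TRUE,
                                  lambda_sd = 3.5, selectivity = 0.1,
                                  max_imf_levels = NULL) {
  if (inherits(imfs, "imf_set")) {
    fs <- fs %||% imfs$fs
    mat <- imfs$imfs
  } else {
    mat <- as.matrix(imfs)
  }
  if (is.null(fs) || is.na(fs)) {
    rlang::abort("fs is required", class = "dusbeats_bad_args")
  }
  if (length(windows) == 0) {
    rlang::abort("window list must be non-empty", class = "dusbeats_bad_args")
  }
  n_imfs <- ncol(mat)
  if (n_imfs == 0) {
    rlang::abort("no IMFs to analyse", class = "dusbeats_no_imf")
  }
  levels <- seq_len(if (is.null(max_imf_levels)) n_imfs else min(max_imf_levels, n_imfs))
  surviving <- if (screen) {
    keep <- vapply(levels, function(i) {
      chebyshev_screen(mat[, i], lambda_sd = lambda_sd, selectivity = selectivity)
    }, logical(1))
    levels[keep]
  } else {
    levels
  }
  if (length(surviving) == 0) {
    rlang::abort(
      paste("no IMF passed the Chebyshev screen; the signal may be noise-only.",
            "Consider relaxing the screen (larger selectivity) or screen = FALSE."),
      class = "dusbeats_no_imf"
    )
  }
  grid <- tidyr::expand_grid(imf_index = surviving, window_ms = windows)
  kv <- purrr::map2(grid$imf_index, grid$window_ms, function(i, w) {
    sliding_kurtosis(mat[, i], fs, w, shift_ms = shift_ms, imf_index = i)
  })
  out <- dplyr::mutate(
    grid,
    n_window_samples = vapply(kv, `[[`, integer(1), "n_window_samples"),
    kv = kv
  )
  attr(out, "fs") <- fs
  class(out) <- c("kurtosis_matrix", class(out))
  out
}
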