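#' Generate a beat-to-beat (RR) interval sequence with target variability
#'
#' Draws `n_beats` intervals around `mean_rr` from a stationary first-order
#' autoregressive (AR(1)) deviation process whose marginal standard deviation
#' equals the SDNN target and whose successive-difference standard deviation
#' equals the RMSSD target. For a stationary AR(1) with lag-1 coefficient
#' `phi` and marginal variance `sigma^2`, the successive-difference variance
#' is `2 sigma^2 (1 - phi)`, so `phi = 1 - RMSSD^2 / (2 SDNN^2)` gives
#' independent closed-form control of both targets. RMSSD > 2 SDNN is
#' unreachable by any stationary process (it would need `phi < -1`) and is
#' rejected.
#'
#' Default targets mirror healthy fetal physiology in mid-gestation: mean RR
#' around 400-420 ms with SDNN of 10-17 ms.
#'
#' @param mean_rr target mean interval (ms), > 0.
#' @param sdnn_target target standard deviation of intervals (ms), >= 0.
#' @param rmssd_target target root-mean-square of successive differences
#'   (ms), >= 0 and <= `2 * sdnn_target`.
#' @param n_beats number of intervals to draw (>= 2).
#' @param seed integer RNG seed; identical seeds give identical sequences.
#' @param bounds physiological clamp applied to each interval, default
#'   `c(250, 800)` ms (75-240 bpm).
#' @return An `rr_sequence`: a tibble with columns `beat` and `interval_ms`,
#'   carrying the generator parameters as attributes.
#' @examples
#' rr <- generate_rr_sequence(406.4, 13.5, 9.5, n_beats = 150, seed = 1)
#' mean(rr$interval_ms)
#' @export
generate_rr_sequence <- function(mean_rr, sdnn_target, rmssd_target, n_beats,
                                 seed = 1, bounds = c(250, 800)) {
  if (!is.numeric(mean_rr) || mean_rr <= 0) {
    rlang::abort("mean_rr must be positive", class = "dusbeats_bad_args")
  }
  if (sdnn_target < 0 || rmssd_target < 0) {
    rlang::abort("sdnn_target and rmssd_target must be non-negative",
                 class = "dusbeats_bad_args")
  }
  if (n_beats < 2) {
    rlang::abort("n_beats must be at least 2", class = "dusbeats_bad_args")
  }
  if (rmssd_target > 2 * sdnn_target) {
    rlang::abort(
      paste0(
        "infeasible target pair: RMSSD (", rmssd_target, ") exceeds 2 * SDNN (",
        2 * sdnn_target, "); no stationary process can reach it"
      ),
      class = "dusbeats_infeasible_targets"
    )
  }
  if (sdnn_target == 0) {
    dev <- rep(0, n_beats)
  } else {
    phi <- 1 - rmssd_target^2 / (2 * sdnn_target^2)
    # phi in [-1, 1]; clamp away from the random-walk boundary so the
    # process stays stationary when RMSSD ~ 0 is requested
    phi <- max(min(phi, 0.999), -0.999)
    innov_sd <- sdnn_target * sqrt(1 - phi^2)
    dev <- with_seed_(seed, {
      d <- numeric(n_beats)
      d[1] <- stats::rnorm(1, 0, sdnn_target)
      eps <- stats::rnorm(n_beats - 1, 0, innov_sd)
      for (k in 2:n_beats) d[k] <- phi * d[k - 1] + eps[k - 1]
      d
    })
  }
  intervals <- pmax(pmin(mean_rr + dev, bounds[2]), bounds[1])
  out <- tibble::tibble(beat = seq_len(n_beats), interval_ms = intervals)
  attr(out, "params") <- list(
    mean_rr = mean_rr, sdnn_target = sdnn_target, rmssd_target = rmssd_target,
    n_beats = n_beats, seed = seed, bounds = bounds
  )
  class(out) <- c("rr_sequence", class(out))
  out
}

rr_intervals <- function(rr) {
  if (is.data.frame(rr) && "interval_ms" %in% names(rr)) {
    return(as.numeric(rr$interval_ms))
  }
  as.numeric(rr)
}
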