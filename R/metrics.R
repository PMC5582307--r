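#' Mean successive beat error
#'
#' Pairs the true and estimated interval vectors *by index* and averages the
#' absolute relative interval error over the first
#' `N_min = min(length(true), length(est))` pairs:
#' `mean(100 * |true(i) - est(i)| / true(i))`. Index pairing means a missed
#' beat shifts all subsequent pairs; [evaluate_record()] additionally logs a
#' time-aligned diagnostic variant that matches beats before differencing.
#'
#' @param true_rr true intervals (ms), all positive.
#' @param est_bb estimated intervals (ms).
#' @return mean percentage error over the `N_min` pairs.
#' @examples
#' successive_beat_error(c(400, 420), c(410, 420))  # 1.25
#' @export
successive_beat_error <- function(true_rr, est_bb) {
  true_rr <- as.numeric(true_rr)
  est_bb <- as.numeric(est_bb)
  if (length(true_rr) == 0 || length(est_bb) == 0) {
    rlang::abort("both interval vectors must be non-empty", class = "dusbeats_bad_args")
  }
  n_min <- min(length(true_rr), length(est_bb))
  tt <- true_rr[seq_len(n_min)]
  if (any(tt <= 0)) {
    rlang::abort("true intervals must be positive", class = "dusbeats_bad_args")
  }
  mean(100 * abs(tt - est_bb[seq_len(n_min)]) / tt)
}

#' Heart-rate-variability summary of an interval series
#'
#' Mean interval, SDNN (sample standard deviation, n-1 denominator) and
#' RMSSD (root mean square of successive differences).
#'
#' @param intervals beat-to-beat intervals (ms), at least 2.
#' @return a one-row tibble with `mean_bb`, `sdnn`, `rmssd`, `n_intervals`.
#' @examples
#' hrv_summary(c(390, 400, 410, 420))  # mean 405, sdnn 12.91, rmssd 10
#' @export
hrv_summary <- function(intervals) {
  intervals <- as.numeric(intervals)
  if (length(intervals) < 2) {
    rlang::abort("need at least 2 intervals", class = "dusbeats_bad_args")
  }
  tibble::tibble(
    mean_bb = mean(intervals),
    sdnn = stats::sd(intervals),
    rmssd = sqrt(mean(diff(intervals)^2)),
    n_intervals = length(intervals)
  )
}

#' Bland-Altman limits of agreement
#'
#' Differences are taken as `true - est`; the limits are
#' `mean(d) +/- 2 * sd(d)`.
#'
#' @param true_vals,est_vals paired measurements, equal length >= 2.
#' @return a one-row tibble with `mean_diff`, `lower_limit`, `upper_limit`.
#' @export
bland_altman <- function(true_vals, est_vals) {
  true_vals <- as.numeric(true_vals)
  est_vals <- as.numeric(est_vals)
  if (length(true_vals) != length(est_vals)) {
    rlang::abort("true and estimated vectors must have equal length",
                 class = "dusbeats_bad_args")
  }
  if (length(true_vals) < 2) {
    rlang::abort("need at least 2 pairs", class = "dusbeats_bad_args")
  }
  d <- true_vals - est_vals
  s <- stats::sd(d)
  tibble::tibble(
    mean_diff = mean(d),
    lower_limit = mean(d) - 2 * s,
    upper_limit = mean(d) + 2 * s
  )
}

#' Evaluate one record's estimated beats against ground truth
#'
#' Computes the signed beat-count mismatch, the mean successive beat error
#' (index-paired), its time-aligned diagnostic variant, the beat-location
#' variability [var_b_loc()], and HRV summaries of both interval series.
#'
#' @param truth,est [beat_series()] objects (each with >= 3 beats so that
#'   interval statistics exist).
#' @return an `evaluation_report`: list with `mismatch_pct`,
#'   `mean_successive_beat_error_pct`, `sbe_aligned_pct`, `var_b_loc_ms`,
#'   `hrv_true`, `hrv_est`, `n_min`, `n_true`, `n_est`.
#' @export
evaluate_record <- function(truth, est) {
  tt <- beat_times(truth)
  et <- beat_times(est)
  if (length(tt) < 3 || length(et) < 3) {
    rlang::abort("need at least 3 beats in each series", class = "dusbeats_bad_args")
  }
  true_rr <- diff(tt)
  est_bb <- diff(et)
  report <- list(
    mismatch_pct = mismatch_error(length(tt), length(et)),
    mean_successive_beat_error_pct = successive_beat_error(true_rr, est_bb),
    sbe_aligned_pct = sbe_time_aligned(tt, et),
    var_b_loc_ms = tryCatch(var_b_loc(truth, est), error = function(e) NA_real_),
    hrv_true = hrv_summary(true_rr),
    hrv_est = hrv_summary(est_bb),
    n_min = min(length(true_rr), length(est_bb)),
    n_true = length(tt),
    n_est = length(et)
  )
  class(report) <- "evaluation_report"
  report
}

# Diagnostic (non-definitional) variant of the successive beat error: match
# estimated beats to true beats in time first, then compare intervals of the
# matched subsequence, so one missed beat does not shift all later pairs.
sbe_time_aligned <- function(tt, et, max_offset_ms = 300) {
  idx <- vapply(et, function(t) which.min(abs(tt - t)), integer(1))
  ok <- abs(tt[idx] - et) <= max_offset_ms
  idx <- idx[ok]
  et <- et[ok]
  keep <- !duplicated(idx)
  idx <- idx[keep]
  et <- et[keep]
  if (length(idx) < 2) return(NA_real_)
  pair_true <- diff(tt[idx])
  pair_est <- diff(et)
  consec <- diff(idx) == 1
  if (!any(consec)) return(NA_real_)
  mean(100 * abs(pair_true[consec] - pair_est[consec]) / pair_true[consec])
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    paste0("<evaluation_report> mismatch %.2f%% | successive beat error %.2f%%",
           " | varB_loc %.2f ms\n  true: %d beats (mean %.1f, SDNN %.1f, RMSSD %.1f ms)",
           "\n  est:  %d beats (mean %.1f, SDNN %.1f, RMSSD %.1f ms)\n"),
    x$mismatch_pct, x$mean_successive_beat_error_pct, x$var_b_loc_ms,
    x$n_true, x$hrv_true$mean_bb, x$hrv_true$sdnn, x$hrv_true$rmssd,
    x$n_est, x$hrv_est$mean_bb, x$hrv_est$sdnn, x$hrv_est$rmssd
  ))
  invisible(x)
}

#' Aggregate evaluation reports over a cohort
#'
#' The signed per-record mismatch errors are aggregated as a root mean
#' square (the only aggregation that yields a single unsigned number per
#' group while penalising over- and under-detection symmetrically); the
#' successive beat error and every HRV field are aggregated as mean and SD.
#'
#' @param reports a list of `evaluation_report` objects.
#' @return a one-row tibble with `n_records`, `mismatch_rms_pct`,
#'   `sbe_mean_pct`, `sbe_sd_pct`, `var_b_loc_mean_ms`, and
#'   `mean_bb`/`sdnn`/`rmssd` means and SDs for both the true and estimated
#'   series.
#' @export
aggregate_cohort <- function(reports) {
  if (inherits(reports, "evaluation_report")) reports <- list(reports)
  if (length(reports) == 0) {
    rlang::abort("no reports to aggregate", class = "dusbeats_bad_args")
  }
  g <- function(f) vapply(reports, function(r) as.numeric(f(r)), numeric(1))
  mm <- g(function(r) r$mismatch_pct)
  sbe <- g(function(r) r$mean_successive_beat_error_pct)
  vb <- g(function(r) r$var_b_loc_ms)
  sd0 <- function(v) if (length(v) > 1) stats::sd(v) else 0
  tibble::tibble(
    n_records = length(reports),
    mismatch_rms_pct = sqrt(mean(mm^2)),
    sbe_mean_pct = mean(sbe),
    sbe_sd_pct = sd0(sbe),
    var_b_loc_mean_ms = mean(vb, na.rm = TRUE),
    mean_bb_true = mean(g(function(r) r$hrv_true$mean_bb)),
    mean_bb_true_sd = sd0(g(function(r) r$hrv_true$mean_bb)),
    mean_bb_est = mean(g(function(r) r$hrv_est$mean_bb)),
    mean_bb_est_sd = sd0(g(function(r) r$hrv_est$mean_bb)),
    sdnn_true = mean(g(function(r) r$hrv_true$sdnn)),
    sdnn_true_sd = sd0(g(function(r) r$hrv_true$sdnn)),
    sdnn_est = mean(g(function(r) r$hrv_est$sdnn)),
    sdnn_est_sd = sd0(g(function(r) r$hrv_est$sdnn)),
    rmssd_true = mean(g(function(r) r$hrv_true$rmssd)),
    rmssd_true_sd = sd0(g(function(r) r$hrv_true$rmssd)),
    rmssd_est = mean(g(function(r) r$hrv_est$rmssd)),
    rmssd_est_sd = sd0(g(function(r) r$hrv_est$rmssd))
  )
}
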