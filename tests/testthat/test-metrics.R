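test_that("successive beat error follows the index-paired definition", {
  expect_equal(successive_beat_error(c(400, 420), c(400, 420)), 0)
  expect_equal(successive_beat_error(c(400, 420), c(410, 420)), 1.25)
  # averaging runs over exactly N_min terms
  long_true <- c(400, 410, 420, 430, 440)
  short_est <- c(404, 410, 420)
  expect_equal(successive_beat_error(long_true, short_est),
               mean(c(100 * 4 / 400, 0, 0)))
  expect_equal(successive_beat_error(long_true, short_est),
               successive_beat_error(long_true[1:3], short_est))
  expect_error(successive_beat_error(c(400, -1), c(400, 400)),
               class = "dusbeats_bad_args")
})

test_that("HRV summary reproduces hand-computed values", {
  h <- hrv_summary(c(390, 400, 410, 420))
  expect_equal(h$mean_bb, 405)
  expect_equal(h$sdnn, sqrt(500 / 3), tolerance = 1e-10)
  expect_equal(h$sdnn, 12.90994, tolerance = 1e-5)
  expect_equal(h$rmssd, 10)
  expect_equal(hrv_summary(c(400, 400, 400))[, 1:3],
               tibble::tibble(mean_bb = 400, sdnn = 0, rmssd = 0))
  expect_equal(hrv_summary(c(380, 417))$rmssd, 37)
  expect_error(hrv_summary(400), class = "dusbeats_bad_args")
})

test_that("HRV summary is order-insensitive except for RMSSD", {
  iv <- c(390, 405, 398, 430, 411, 402)
  perm <- c(4, 1, 6, 3, 5, 2)
  a <- hrv_summary(iv)
  b <- hrv_summary(iv[perm])
  expect_equal(a$mean_bb, b$mean_bb)
  expect_equal(a$sdnn, b$sdnn)
  expect_false(isTRUE(all.equal(a$rmssd, b$rmssd)))
})

test_that("Bland-Altman limits are mean +/- 2 SD of the differences", {
  ba0 <- bland_altman(c(400, 410, 420), c(400, 410, 420))
  expect_equal(unlist(ba0), c(mean_diff = 0, lower_limit = 0, upper_limit = 0))
  ba <- bland_altman(c(1, 0), c(0, 1))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$upper_limit, 2 * sd(c(1, -1)), tolerance = 1e-12)
  expect_equal(ba$upper_limit, 2.828427, tolerance = 1e-6)
  expect_equal(ba$lower_limit, -ba$upper_limit)
  # limits always symmetric about the mean difference
  withr::with_seed(3, {
    tv <- rnorm(20, 400, 10); ev <- rnorm(20, 398, 12)
    bb <- bland_altman(tv, ev)
    expect_equal(bb$upper_limit - bb$mean_diff, bb$mean_diff - bb$lower_limit)
  })
  expect_error(bland_altman(1:3, 1:4), class = "dusbeats_bad_args")
})

test_that("evaluating an estimate against itself gives zero errors", {
  truth <- beat_series(cumsum(c(350, rep(c(395, 405, 410), 6))))
  rep <- evaluate_record(truth, truth)
  expect_equal(rep$mismatch_pct, 0)
  expect_equal(rep$mean_successive_beat_error_pct, 0)
  expect_equal(rep$var_b_loc_ms, 0)
  expect_identical(rep$hrv_true, rep$hrv_est)
})

test_that("over-detection yields a negative mismatch in the report", {
  truth <- beat_series(seq(400, 6000, by = 400))
  est <- beat_series(sort(c(seq(400, 6000, by = 400), 3100)))
  rep <- evaluate_record(truth, est)
  expect_lt(rep$mismatch_pct, 0)
})

test_that("a full pipeline evaluation report has finite fields", {
  rec <- make_record(13, n_beats = 60, snr_db = 10)
  est <- estimate_fhr(rec$dus, test_config(max_imfs = 5))
  rep <- evaluate_record(rec$true_beats, est)
  g <- glance(rep)
  expect_true(all(vapply(g[, c("mismatch_pct", "sbe_pct", "var_b_loc_ms",
                               "mean_bb_est", "sdnn_est", "rmssd_est")],
                         is.finite, logical(1))))
  expect_equal(rep$n_min, min(rep$n_true, rep$n_est) - 1)
})

test_that("cohort aggregation uses RMS for mismatch and mean/SD elsewhere", {
  mk <- function(mm) {
    truth <- beat_series(seq(400, 20000, by = 400))
    n_est <- round(nrow(truth) * (1 - mm / 100))
    est <- beat_series(seq(400, by = 400, length.out = n_est))
    evaluate_record(truth, est)
  }
  r1 <- mk(0)
  agg1 <- aggregate_cohort(list(r1))
  expect_equal(agg1$mismatch_rms_pct, abs(r1$mismatch_pct))
  # RMS of {+3, -4} style signed mismatches
  fake <- function(mm) { r <- r1; r$mismatch_pct <- mm; r }
  agg2 <- aggregate_cohort(list(fake(3), fake(-4)))
  expect_equal(agg2$mismatch_rms_pct, sqrt((9 + 16) / 2))
  expect_equal(agg2$mismatch_rms_pct, 3.535534, tolerance = 1e-6)
  # identical reports: zero SDs
  agg3 <- aggregate_cohort(list(r1, r1, r1))
  expect_equal(agg3$sbe_sd_pct, 0)
  expect_equal(agg3$sdnn_est_sd, 0)
  expect_error(aggregate_cohort(list()), class = "dusbeats_bad_args")
})

test_that("cohort RMS dominates the absolute mean of signed mismatches", {
  withr::with_seed(5, {
    truth <- beat_series(seq(400, 20000, by = 400))
    base <- evaluate_record(truth, truth)
    reports <- lapply(rnorm(12, 0, 3), function(mm) {
      r <- base; r$mismatch_pct <- mm; r
    })
    agg <- aggregate_cohort(reports)
    expect_gte(agg$mismatch_rms_pct,
               abs(mean(vapply(reports, `[[`, numeric(1), "mismatch_pct"))))
  })
})
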