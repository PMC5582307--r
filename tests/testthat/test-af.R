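test_that("the envelope recovers a Gaussian burst window", {
  fs <- 1000
  t_ms <- seq(-200, 200)
  w <- exp(-t_ms^2 / (2 * 40^2))
  x <- dus_signal(w * sin(2 * pi * 80 * t_ms / 1000), fs)
  env <- dus_envelope(x)
  expect_gt(cor(env$samples, w), 0.95)
  expect_true(all(env$samples >= 0))
})

test_that("a zero signal has a zero envelope", {
  env <- dus_envelope(dus_signal(numeric(1000), 1000))
  expect_lt(max(abs(env$samples)), 1e-9)
})

test_that("autocorrelation periodicity finds the burst-train period", {
  rr <- generate_rr_sequence(400, 0, 0, 10, seed = 1)
  rec <- synthesize_dus(rr, snr_db = 40, jitter_sd = 0, seed = 1)
  env <- dus_envelope(rec$dus)$samples
  p <- af_periodicity(env[1:2000], fs = 1000, lag_range = c(250, 800))
  expect_lt(abs(p - 400), 2.5)
})

test_that("white-noise windows are reported unreliable", {
  res <- vapply(1:20, function(s) {
    withr::with_seed(s, af_periodicity(rnorm(2000), fs = 1000))
  }, numeric(1))
  expect_true(all(is.na(res)))
})

test_that("a period outside the searched lag range is unreliable", {
  # burst train with a 1000 ms period: nothing in [250, 800] matches
  env <- rep(c(rep(1, 50), rep(0, 950)), 3)[1:2600]
  p <- af_periodicity(env, fs = 1000, lag_range = c(250, 800))
  expect_true(is.na(p))
})

test_that("the window precondition is enforced", {
  expect_error(af_periodicity(rnorm(1000), fs = 1000, lag_range = c(250, 800)),
               class = "dusbeats_bad_args")
})

test_that("AF recovers constant-rate intervals on a clean record", {
  # strictly periodic morphology: beat-to-beat burst variation is a separate
  # generator feature, not part of the AF accuracy contract
  strict <- dus_burst_params(amp_cv = 0, width_cv = 0, wall_offset_sd_ms = 0)
  rr <- generate_rr_sequence(400, 0, 0, 150, seed = 1)
  rec <- synthesize_dus(rr, snr_db = 40, jitter_sd = 0, seed = 1, params = strict)
  beats <- af_estimate(rec$dus)
  iv <- beat_intervals(beats)
  expect_true(all(iv >= 395 & iv <= 405))
  expect_true(all(iv >= 250 & iv <= 800))
})

test_that("AF converges within a few beats after a step change in rate", {
  iv <- c(rep(400, 75), rep(450, 75))
  rec <- synthesize_dus(tibble::tibble(interval_ms = iv), snr_db = 40,
                        jitter_sd = 0, seed = 1)
  beats <- af_estimate(rec$dus)
  est_iv <- beat_intervals(beats)
  step_time <- sum(iv[1:75])
  after <- which(beats$beat_time_ms[-1] > step_time + 5 * 450)
  expect_gt(length(after), 5)
  settled <- est_iv[utils::tail(after, 10)]
  expect_true(all(abs(settled - 450) <= 5))
})

test_that("AF is deterministic and rejects hopeless noise", {
  rec <- make_record(5, n_beats = 60, snr_db = 10)
  a <- af_estimate(rec$dus)
  b <- af_estimate(rec$dus)
  expect_identical(a$beat_time_ms, b$beat_time_ms)
  noise <- dus_signal(withr::with_seed(6, rnorm(20000)), 1000)
  expect_error(af_estimate(noise), class = "dusbeats_af_too_noisy")
  expect_error(af_estimate(dus_signal(rnorm(2000), 1000)),
               class = "dusbeats_bad_args")
})
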