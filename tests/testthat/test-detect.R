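test_that("mismatch error follows its signed definition", {
  expect_equal(mismatch_error(100, 100), 0)
  expect_equal(mismatch_error(150, 147), 2)
  expect_equal(mismatch_error(100, 105), -5)  # over-detection is negative
  expect_error(mismatch_error(0, 10), class = "dusbeats_bad_args")
})

test_that("var_b_loc measures the spread, not the offset, of matched beats", {
  truth <- beat_series(seq(400, 8000, by = 400))
  expect_equal(var_b_loc(truth, truth), 0)
  shifted <- beat_series(seq(400, 8000, by = 400) + 20)
  expect_equal(var_b_loc(truth, shifted), 0)
  jittered <- beat_series(seq(400, 8000, by = 400) + rep(c(5, 15), 10))
  expect_equal(var_b_loc(truth, jittered), sd(rep(c(5, 15), 10)))
  expect_equal(sd(rep(c(5, 15), 2)), 5.773503, tolerance = 1e-6)
  far <- beat_series(seq(400, 8000, by = 400) + 10000)
  expect_error(var_b_loc(truth, far), class = "dusbeats_no_match")
})

test_that("beat detection recovers constructed impulse locations exactly", {
  v <- numeric(5000)
  true_idx <- c(500, 950, 1500, 2000, 2450, 3000, 3500, 4200)
  v[true_idx + 1] <- 5   # value index k corresponds to time (k-1) ms at W = 0
  v <- v + 0.01
  kv <- kurtosis_vector(v, window_ms = 0, fs = 1000, n_window_samples = 0)
  beats <- detect_beats(kv, fs = 1000)
  expect_equal(beats$beat_time_ms, as.numeric(true_idx))
})

test_that("summation aligns vectors of different windows on their centre times", {
  # impulses at the same signal times in two vectors with different windows
  n <- 4000
  t_true <- c(800, 1400, 2000, 2600, 3200)
  mk <- function(w) {
    off <- floor(w / 2)
    len <- n - w + 1
    v <- numeric(len) + 0.01
    v[t_true - off + 1] <- 3  # value index k sits at centre time k - 1 + off
    kurtosis_vector(v, window_ms = w, fs = 1000)
  }
  beats <- detect_beats(list(mk(100), mk(200)), fs = 1000)
  expect_equal(beats$beat_time_ms, as.numeric(t_true))
})

test_that("the refractory rule keeps only the taller of two close peaks", {
  v <- numeric(2000) + 0.01
  v[501] <- 2   # 500 ms
  v[701] <- 1   # 200 ms later
  v[1501] <- 1.5
  kv <- kurtosis_vector(v, window_ms = 0, fs = 1000, n_window_samples = 0)
  beats <- detect_beats(kv, fs = 1000, min_distance_ms = 300)
  expect_equal(beats$beat_time_ms, c(500, 1500))
})

test_that("no two detected beats are ever closer than the minimum distance", {
  withr::with_seed(21, {
    for (i in 1:20) {
      v <- abs(rnorm(4000))^3
      kv <- kurtosis_vector(v, window_ms = 0, fs = 1000, n_window_samples = 0)
      beats <- detect_beats(kv, fs = 1000, min_distance_ms = 300)
      if (nrow(beats) > 1) expect_true(all(diff(beats$beat_time_ms) >= 300))
    }
  })
})

test_that("an empty vector list is rejected", {
  expect_error(detect_beats(list(), fs = 1000), class = "dusbeats_bad_args")
})

test_that("default-mode selection returns the preset grid restricted to the matrix", {
  rec <- make_short_record(9, snr_db = 15)
  dec <- eemd(denoise_wavelet(rec$dus), ensemble_size = 5,
              noise_sd_fraction = 0.2, seed = 2, max_imfs = 4)
  km <- build_kurtosis_matrix(dec, screen = FALSE)
  sel <- select_vectors(km)
  expect_identical(sel$mode, "default")
  expect_true(all(sel$selected$imf_index %in% 1:3))
  expect_setequal(unique(sel$selected$window_ms), c(300, 350, 400))
  expect_equal(nrow(sel$selected), length(intersect(1:3, unique(km$imf_index))) * 3)
})

test_that("a single-vector matrix selects that vector in calibrated mode", {
  rec <- make_short_record(9, snr_db = 15)
  dec <- eemd(denoise_wavelet(rec$dus), ensemble_size = 5,
              noise_sd_fraction = 0.2, seed = 2, max_imfs = 2)
  km <- build_kurtosis_matrix(dec, windows = 350, screen = FALSE,
                              max_imf_levels = 1)
  sel <- select_vectors(km, truth = rec$true_beats)
  expect_identical(sel$mode, "calibrated")
  expect_equal(nrow(sel$selected), 1)
  expect_equal(sel$selected$window_ms, 350)
})

test_that("calibrated mode requires non-empty truth", {
  rec <- make_short_record(9)
  dec <- emd(rec$dus, max_imfs = 2)
  km <- build_kurtosis_matrix(dec, windows = c(300, 350), screen = FALSE)
  expect_error(select_vectors(km, truth = numeric(0)), class = "dusbeats_bad_args")
})

test_that("the full pipeline is deterministic and rejects degenerate inputs", {
  rec <- make_short_record(10, snr_db = 10)
  cfg <- test_config(max_imfs = 5)
  a <- estimate_fhr(rec$dus, cfg)
  b <- estimate_fhr(rec$dus, cfg)
  expect_identical(a$beat_time_ms, b$beat_time_ms)
  expect_true(all(diff(a$beat_time_ms) >= cfg$min_distance_ms))
  # pure noise must error out (no informative IMF), not fabricate beats
  noise <- dus_signal(withr::with_seed(4, rnorm(30000)), 1000)
  expect_error(estimate_fhr(noise, cfg), class = "dusbeats_no_imf")
  expect_error(estimate_fhr(dus_signal(rnorm(2000), 1000), cfg),
               class = "dusbeats_bad_args")
})

test_that("pipeline accuracy on a standard record is within a few percent", {
  rec <- make_record(12, snr_db = 10)
  est <- estimate_fhr(rec$dus, test_config())
  rep <- evaluate_record(rec$true_beats, est)
  expect_lt(abs(rep$mismatch_pct), 5)
  expect_true(is.finite(rep$var_b_loc_ms))
})
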