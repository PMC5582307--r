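test_that("the kurtosis ratio matches its closed forms", {
  expect_equal(kurtosis_ratio(rep(3, 10)), 9 / 10)
  expect_equal(kurtosis_ratio(rep(-0.2, 10)), 9 / 10)
  expect_equal(kurtosis_ratio(c(5, numeric(9))), 9)
  expect_equal(kurtosis_ratio(numeric(10)), 0)   # silent window is defined as 0
  expect_error(kurtosis_ratio(1), class = "dusbeats_bad_args")
})

test_that("the kurtosis ratio of a long Gaussian sample approaches 3", {
  vals <- vapply(1:20, function(s) {
    withr::with_seed(s, kurtosis_ratio(rnorm(1e5)))
  }, numeric(1))
  expect_true(all(abs(vals - 3) < 0.1))
})

test_that("sliding kurtosis equals the brute-force window evaluation", {
  withr::with_seed(11, {
    for (i in 1:5) {
      x <- rnorm(300) * sample(c(1, 5), 300, replace = TRUE)
      w <- sample(c(10, 25, 50), 1)
      kv <- sliding_kurtosis(x, fs = 1000, window_ms = w)
      expect_equal(kv$values, brute_sliding_kurtosis(x, kv$n_window_samples),
                   tolerance = 1e-10)
    }
  })
})

test_that("sliding kurtosis keeps its length contract and constant-window value", {
  x <- rep(1, 60000)
  kv <- sliding_kurtosis(x, fs = 1000, window_ms = 300)
  expect_length(kv$values, 59701)
  expect_true(all(abs(kv$values - 299 / 300) < 1e-12))
  kv100 <- sliding_kurtosis(rep(0.5, 2000), fs = 1000, window_ms = 100)
  expect_true(all(abs(kv100$values - 99 / 100) < 1e-12))
})

test_that("an isolated impulse maximises sliding kurtosis near its location", {
  x <- numeric(2000)
  x[700] <- 1
  x <- x + withr::with_seed(2, rnorm(2000, 0, 1e-3))
  kv <- sliding_kurtosis(x, fs = 1000, window_ms = 100)
  peak_start <- which.max(kv$values)
  expect_true(abs(peak_start - 700) <= kv$n_window_samples)
})

test_that("window bounds are validated", {
  expect_error(sliding_kurtosis(rnorm(100), 1000, window_ms = 500),
               class = "dusbeats_bad_args")
  expect_error(sliding_kurtosis(rnorm(100), 1000, window_ms = 1),
               class = "dusbeats_bad_args")
})

test_that("the Chebyshev screen separates heavy-tailed from noise-like vectors", {
  # white Gaussian: fails across seeds
  gauss <- vapply(1:20, function(s) {
    withr::with_seed(s, chebyshev_screen(rnorm(20000)))
  }, logical(1))
  expect_false(any(gauss))
  # sparse large excursions: passes
  v <- numeric(2000)
  v[seq(50, 2000, by = 100)] <- 10
  expect_true(chebyshev_screen(v))
  base <- withr::with_seed(1, rnorm(2000, 0, 0.05))
  expect_true(chebyshev_screen(base + v))
  # constant: zero variance fails
  expect_false(chebyshev_screen(rep(4, 100)))
})

test_that("the kurtosis matrix keeps one vector per surviving IMF and window", {
  rec <- make_short_record(7, snr_db = 10)
  dec <- eemd(denoise_wavelet(rec$dus), ensemble_size = 5,
              noise_sd_fraction = 0.2, seed = 2, max_imfs = 3)
  km <- build_kurtosis_matrix(dec, screen = FALSE)
  expect_s3_class(km, "kurtosis_matrix")
  expect_equal(nrow(km), dec$n_imfs * 12)
  expect_setequal(unique(km$window_ms), seq(50, 600, by = 50))
  expect_true(all(vapply(km$kv, function(v) all(v$values >= 0), logical(1))))
})

test_that("burst-carrying IMFs survive screening; pure noise does not", {
  rec <- make_record(8, n_beats = 60, snr_db = 10)
  dec <- eemd(denoise_wavelet(rec$dus), ensemble_size = 5,
              noise_sd_fraction = 0.2, seed = 2, max_imfs = 5)
  km <- build_kurtosis_matrix(dec)
  expect_true(length(unique(km$imf_index)) >= 1)
  noise <- dus_signal(withr::with_seed(3, rnorm(30000)), 1000)
  ndec <- eemd(denoise_wavelet(noise), ensemble_size = 5,
               noise_sd_fraction = 0.2, seed = 2, max_imfs = 5)
  expect_error(build_kurtosis_matrix(ndec), class = "dusbeats_no_imf")
})

test_that("an empty window list is rejected", {
  rec <- make_short_record(7, n_beats = 20)
  dec <- emd(rec$dus, max_imfs = 3)
  expect_error(build_kurtosis_matrix(dec, windows = numeric(0)),
               class = "dusbeats_bad_args")
})
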