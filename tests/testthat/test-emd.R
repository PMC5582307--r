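test_that("a pure tone sifts to itself", {
  t <- seq(0, 2, by = 1e-3)
  x <- sin(2 * pi * 10 * t)
  imf <- emd_sift(x)
  expect_gt(cor(imf, x), 0.99)
})

test_that("a monotone signal signals a monotone residue", {
  expect_error(emd_sift(seq(0, 1, length.out = 500)),
               class = "dusbeats_monotone_residue")
})

test_that("a two-tone mixture separates into its components", {
  t <- seq(0, 2, by = 1e-3)
  hi <- sin(2 * pi * 50 * t)
  lo <- sin(2 * pi * 2 * t)
  dec <- emd(hi + lo, fs = 1000)
  expect_gte(dec$n_imfs, 2)
  interior <- seq(floor(length(t) * 0.05), ceiling(length(t) * 0.95))
  expect_gt(cor(dec$imfs[interior, 1], hi[interior]), 0.95)
})

test_that("EMD reconstruction telescopes to the input", {
  for (x in emd_test_signals(n = 1024, n_random = 3)) {
    dec <- emd(x, fs = 1000)
    recon <- if (dec$n_imfs > 0) rowSums(dec$imfs) + dec$residue else dec$residue
    expect_lt(sqrt(mean((recon - x)^2)) / sqrt(mean(x^2)), 1e-8)
  }
})

test_that("a constant signal yields no IMFs and itself as residue", {
  x <- rep(2.5, 600)
  dec <- emd(x, fs = 1000)
  expect_identical(dec$n_imfs, 0L)
  expect_identical(dec$residue, x)
})

test_that("zero-crossing rate decreases over the leading IMFs of structured mixtures", {
  t <- seq(0, 2.047, by = 1e-3)
  x <- sin(2 * pi * 80 * t) + sin(2 * pi * 25 * t) + sin(2 * pi * 5 * t)
  dec <- emd(x, fs = 1000)
  zr <- vapply(seq_len(min(dec$n_imfs, 3)), function(k) {
    count_extrema_zc(dec$imfs[, k])$n_zero_crossings
  }, numeric(1))
  expect_true(all(diff(zr) <= 0))
})

test_that("EEMD with a single member and no noise equals EMD exactly", {
  rec <- make_short_record(6, n_beats = 20)
  a <- eemd(rec$dus, ensemble_size = 1, noise_sd_fraction = 0, seed = 1, max_imfs = 6)
  b <- emd(rec$dus, max_imfs = 6)
  expect_identical(a$imfs, b$imfs)
  expect_identical(a$residue, b$residue)
})

test_that("EEMD is deterministic under a fixed seed", {
  t <- seq(0, 1.5, by = 1e-3)
  x <- sin(2 * pi * 40 * t) + sin(2 * pi * 3 * t)
  a <- eemd(x, ensemble_size = 10, noise_sd_fraction = 0.2, seed = 9, fs = 1000)
  b <- eemd(x, ensemble_size = 10, noise_sd_fraction = 0.2, seed = 9, fs = 1000)
  expect_identical(a$imfs, b$imfs)
  c <- eemd(x, ensemble_size = 10, noise_sd_fraction = 0.2, seed = 10, fs = 1000)
  expect_false(identical(a$imfs, c$imfs))
})

test_that("EEMD reconstruction error shrinks with the ensemble average of the noise", {
  t <- seq(0, 2, by = 1e-3)
  x <- sin(2 * pi * 50 * t) + sin(2 * pi * 2 * t)
  E <- 100
  frac <- 0.2
  dec <- eemd(x, ensemble_size = E, noise_sd_fraction = frac, seed = 1,
              max_imfs = 8, fs = 1000)
  recon <- rowSums(dec$imfs) + dec$residue
  err <- sqrt(mean((recon - x)^2))
  expect_lte(err, 3 * frac * sd(x) / sqrt(E))
})
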