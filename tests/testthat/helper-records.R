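# Shared fixtures, all generated in code.

# A standard study-scale record: 1-minute equivalent, mean RR 400 ms.
make_record <- function(seed, mean_rr = 400, sdnn = 13.5, rmssd = 9.5,
                        n_beats = 150, snr_db = 10, jitter_sd = 5, ...) {
  rr <- generate_rr_sequence(mean_rr, sdnn, rmssd, n_beats, seed = seed)
  synthesize_dus(rr, snr_db = snr_db, jitter_sd = jitter_sd, seed = seed + 1000L, ...)
}

# Short record for fast unit tests (~16 s).
make_short_record <- function(seed, n_beats = 40, ...) {
  make_record(seed, n_beats = n_beats, ...)
}

# Pipeline configuration at test scale: a reduced EEMD ensemble and mode cap
# keep a full run of a 1-minute record around ten seconds without changing
# any detection-stage parameter.
test_config <- function(seed = 2, ensemble_size = 10, max_imfs = 6, ...) {
  fhr_config(ensemble_size = ensemble_size, max_imfs = max_imfs, seed = seed, ...)
}

# Brute-force sliding kurtosis: the independent oracle for the O(n)
# cumulative-sum implementation.
brute_sliding_kurtosis <- function(x, w) {
  vapply(seq_len(length(x) - w + 1), function(k) {
    win <- x[k:(k + w - 1)]
    s2 <- sum(win^2)
    if (s2 == 0) 0 else (w - 1) * sum(win^4) / s2^2
  }, numeric(1))
}

# Structured + random signal family used for decomposition invariants.
emd_test_signals <- function(n = 2048, n_random = 10, seed = 42) {
  withr::with_seed(seed, {
    t <- seq(0, (n - 1) / 1000, by = 1e-3)
    sigs <- lapply(seq_len(n_random), function(i) {
      as.numeric(stats::arima.sim(list(ar = 0.9), n)) + stats::rnorm(n) * 0.2
    })
    c(sigs, list(
      sin(2 * pi * 50 * t) + sin(2 * pi * 2 * t),
      sin(2 * pi * 30 * t) * exp(-((t - 1) / 0.3)^2) + 0.5 * sin(2 * pi * 3 * t),
      sin(2 * pi * (5 * t + 20 * t^2)),
      sign(sin(2 * pi * 5 * t)) + 0.1 * stats::rnorm(n),
      cumsum(stats::rnorm(n)) * 0.05 + sin(2 * pi * 20 * t),
      sin(2 * pi * 80 * t) + sin(2 * pi * 25 * t) + sin(2 * pi * 5 * t),
      abs(sin(2 * pi * 4 * t)) + 0.2 * stats::rnorm(n),
      stats::rnorm(n),
      sin(2 * pi * 10 * t) * (1 + 0.5 * sin(2 * pi * 0.5 * t)),
      exp(-t) * sin(2 * pi * 15 * t) + 0.3 * stats::rnorm(n)
    ))
  })
}
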