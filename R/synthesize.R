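#' Burst-model parameters for the synthetic DUS generator
#'
#' Each cardiac cycle contributes three Gaussian-windowed tone bursts plus a
#' continuous low-level clutter floor:
#'
#' * a systolic valve click (S1 analogue): short, high-frequency, at the beat
#'   time;
#' * sustained ventricular wall motion: low-frequency, lasting through
#'   systole, centred `wall_offset_ms` after the beat;
#' * a diastolic valve click (S2 analogue): short, mid-frequency, a fixed
#'   fraction of the current cycle after the beat -- both valve-click groups
#'   are prominent in fetal Doppler audio;
#' * diffuse tissue backscatter ("clutter"): band-limited continuous noise at
#'   a small fraction of the burst amplitude; a continuous-wave probe always
#'   returns some moving-tissue signal between beats.
#'
#' The valve and wall scales are deliberately separable by EMD. Beat-to-beat
#' variability of real recordings is emulated by lognormal amplitude
#' variation (`amp_cv`), lognormal width variation (`width_cv`) and Gaussian
#' jitter of the wall-motion offset, so which component dominates a cycle --
#' and its exact shape -- changes from beat to beat, as it does when the
#' insonation angle drifts.
#'
#' @param valve_freq_hz,wall_freq_hz,dia_freq_hz carrier frequencies (Hz).
#' @param valve_width_ms,wall_width_ms,dia_width_ms effective burst widths
#'   (ms); the Gaussian window SD is width / 6 so the burst decays to ~1% at
#'   the edge.
#' @param wall_offset_ms centre of the wall-motion burst after the beat time
#'   (ms); jittered per beat with SD `wall_offset_sd_ms`.
#' @param dia_fraction position of the diastolic click as a fraction of the
#'   current beat-to-beat interval (default 0.55).
#' @param valve_amp,wall_amp,dia_amp mean burst amplitudes (arbitrary units).
#' @param amp_cv lognormal sigma of the per-beat amplitude variation
#'   (default 0.35; 0 for fixed amplitudes).
#' @param width_cv lognormal sigma of the per-beat width variation
#'   (default 0.25).
#' @param wall_offset_sd_ms SD of the per-beat wall-offset jitter (ms).
#' @param clutter_amp clutter RMS as a fraction of the burst RMS
#'   (default 0.15; 0 for no clutter).
#' @param clutter_band_hz passband of the clutter component (Hz).
#' @return a named list of generator parameters.
#' @export
dus_burst_params <- function(valve_freq_hz = 80, valve_width_ms = 30,
                             wall_freq_hz = 25, wall_width_ms = 180,
                             wall_offset_ms = 90,
                             dia_freq_hz = 60, dia_width_ms = 35,
                             dia_fraction = 0.55,
                             valve_amp = 1.0, wall_amp = 0.8, dia_amp = 0.9,
                             amp_cv = 0.35, width_cv = 0.25,
                             wall_offset_sd_ms = 10,
                             clutter_amp = 0.15,
                             clutter_band_hz = c(15, 100)) {
  list(
    valve_freq_hz = valve_freq_hz, valve_width_ms = valve_width_ms,
    wall_freq_hz = wall_freq_hz, wall_width_ms = wall_width_ms,
    wall_offset_ms = wall_offset_ms,
    dia_freq_hz = dia_freq_hz, dia_width_ms = dia_width_ms,
    dia_fraction = dia_fraction,
    valve_amp = valve_amp, wall_amp = wall_amp, dia_amp = dia_amp,
    amp_cv = amp_cv, width_cv = width_cv,
    wall_offset_sd_ms = wall_offset_sd_ms,
    clutter_amp = clutter_amp, clutter_band_hz = clutter_band_hz
  )
}

#' Synthesize a DUS-like record with known ground-truth beats
#'
#' Places the systolic (valve click + wall motion) and diastolic bursts of
#' each cardiac cycle at jittered beat times (cumulative RR intervals plus
#' zero-mean Gaussian jitter, modelling the beat-to-beat variability of the
#' electromechanical delay), adds the continuous clutter floor, then adds
#' white Gaussian noise scaled so that the ratio of burst power to noise
#' power *on the burst-support samples* equals `snr_db`. Restricting the SNR definition
#' to burst support keeps the nominal SNR meaningful: the silence between
#' bursts would otherwise deflate it.
#'
#' The record starts half a cycle before the first beat and ends half a cycle
#' after the last, so `n_beats` intervals of mean `m` give a duration of
#' about `n_beats * m` ms (150 beats at 400 ms is a 1-minute record).
#'
#' @param rr an `rr_sequence` from [generate_rr_sequence()] (or a numeric
#'   vector of intervals in ms); must be non-empty.
#' @param fs sampling rate in Hz, >= 500 (default 1000, the usual clinical
#'   acquisition rate).
#' @param snr_db target burst-to-noise power ratio in dB; `Inf` for a clean
#'   record.
#' @param jitter_sd SD of the beat-time jitter (ms). Jitter is clamped to
#'   +/- 49% of the shortest interval so beat ordering is always preserved.
#' @param seed integer RNG seed (jitter and noise).
#' @param params burst model from [dus_burst_params()].
#' @return A `synthetic_record`: list with `dus` (the noisy [dus_signal()]),
#'   `true_beats` (a [beat_series()]), the stored `clean` and `noise`
#'   components, `support` (logical burst-support mask), `snr_db`, and
#'   `params`.
#' @examples
#' rr <- generate_rr_sequence(400, 0, 0, n_beats = 20, seed = 1)
#' rec <- synthesize_dus(rr, snr_db = 20, jitter_sd = 0, seed = 1)
#' rec$true_beats
#' @export
synthesize_dus <- function(rr, fs = 1000, snr_db = 10, jitter_sd = 5,
                           seed = 1, params = dus_burst_params()) {
  intervals <- rr_intervals(rr)
  if (length(intervals) == 0) {
    rlang::abort("rr must be non-empty", class = "dusbeats_bad_args")
  }
  if (fs < 500) {
    rlang::abort("fs must be at least 500 Hz", class = "dusbeats_bad_args")
  }
  n_beats <- length(intervals)
  lead_ms <- intervals[1] / 2
  base_times <- lead_ms + cumsum(c(0, intervals[-1]))
  duration_ms <- base_times[n_beats] + intervals[1] / 2
  n_samp <- as.integer(round(duration_ms / 1000 * fs))

  jitter_lim <- 0.49 * min(intervals)
  comp <- with_seed_(seed, {
    j <- if (jitter_sd > 0) stats::rnorm(n_beats, 0, jitter_sd) else rep(0, n_beats)
    j <- pmax(pmin(j, jitter_lim), -jitter_lim)
    beat_ms <- base_times + j
    beat_ms <- pmin(pmax(beat_ms, 0), duration_ms)

    clean <- numeric(n_samp)
    support <- logical(n_samp)
    add_burst <- function(center_ms, freq_hz, width_ms, amp) {
      sd_ms <- width_ms / 6
      half <- 4 * sd_ms
      i0 <- max(1L, ms_to_samples(center_ms - half, fs) + 1L)
      i1 <- min(n_samp, ms_to_samples(center_ms + half, fs) + 1L)
      if (i1 < i0) return(invisible())
      idx <- i0:i1
      t_ms <- samples_to_ms(idx - 1, fs) - center_ms
      w <- exp(-t_ms^2 / (2 * sd_ms^2))
      clean[idx] <<- clean[idx] + amp * w * sin(2 * pi * freq_hz * t_ms / 1000)
      support[idx] <<- TRUE
      invisible()
    }
    amp_cv <- params$amp_cv %||% 0
    width_cv <- params$width_cv %||% 0
    lnvar <- function(cv) {
      if (cv > 0) exp(stats::rnorm(n_beats, 0, cv)) else rep(1, n_beats)
    }
    g_valve <- lnvar(amp_cv); g_wall <- lnvar(amp_cv); g_dia <- lnvar(amp_cv)
    w_valve <- lnvar(width_cv); w_wall <- lnvar(width_cv); w_dia <- lnvar(width_cv)
    off_sd <- params$wall_offset_sd_ms %||% 0
    wall_off <- params$wall_offset_ms +
      (if (off_sd > 0) stats::rnorm(n_beats, 0, off_sd) else numeric(n_beats))
    # diastolic click sits a fixed fraction into the current cycle
    cycle <- c(intervals[-1], intervals[length(intervals)])
    for (k in seq_len(n_beats)) {
      add_burst(beat_ms[k], params$valve_freq_hz,
                params$valve_width_ms * w_valve[k], params$valve_amp * g_valve[k])
      add_burst(beat_ms[k] + wall_off[k], params$wall_freq_hz,
                params$wall_width_ms * w_wall[k], params$wall_amp * g_wall[k])
      if ((params$dia_amp %||% 0) > 0) {
        add_burst(beat_ms[k] + params$dia_fraction * cycle[k],
                  params$dia_freq_hz, params$dia_width_ms * w_dia[k],
                  params$dia_amp * g_dia[k])
      }
    }
    p_burst <- mean(clean[support]^2)
    clutter_amp <- params$clutter_amp %||% 0
    if (clutter_amp > 0) {
      bf <- signal::butter(2, params$clutter_band_hz / (fs / 2), type = "pass")
      clut <- signal::filtfilt(bf, stats::rnorm(n_samp))
      clut <- clut / sqrt(mean(clut^2)) * sqrt(p_burst) * clutter_amp
      clean <- clean + clut
    }
    if (is.finite(snr_db)) {
      noise_sd <- sqrt(p_burst / 10^(snr_db / 10))
      noise <- stats::rnorm(n_samp, 0, noise_sd)
    } else {
      noise <- numeric(n_samp)
    }
    list(clean = clean, noise = noise, support = support, beat_ms = beat_ms)
  })

  structure(
    list(
      dus = dus_signal(comp$clean + comp$noise, fs = fs, label = "synthetic DUS"),
      true_beats = beat_series(comp$beat_ms),
      clean = comp$clean,
      noise = comp$noise,
      support = comp$support,
      snr_db = snr_db,
      params = c(params, list(fs = fs, jitter_sd = jitter_sd, seed = seed,
                              duration_ms = duration_ms))
    ),
    class = "synthetic_record"
  )
}

#' @export
print.synthetic_record <- function(x, ...) {
  cat(sprintf(
    "<synthetic_record> %.1f s @ %g Hz, %d beats, nominal SNR %s dB (measured %.1f dB)\n",
    x$params$duration_ms / 1000, x$params$fs, nrow(x$true_beats),
    format(x$snr_db), measured_snr_db(x)
  ))
  invisible(x)
}

#' Empirical SNR of a synthetic record
#'
#' Recomputes the burst-to-noise power ratio from the stored clean and noise
#' components over the burst-support samples; by construction it matches the
#' nominal `snr_db` up to the sampling error of the noise power.
#'
#' @param record a `synthetic_record`.
#' @return SNR in dB (`Inf` for a clean record).
#' @export
measured_snr_db <- function(record) {
  stopifnot(inherits(record, "synthetic_record"))
  p_n <- mean(record$noise[record$support]^2)
  if (p_n == 0) return(Inf)
  10 * log10(mean(record$clean[record$support]^2) / p_n)
}
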