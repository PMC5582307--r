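# dusbeats

Beat-to-beat fetal heart intervals from continuous Doppler ultrasound, via
empirical mode decomposition and sliding-window kurtosis.

Doppler-based cardiotocography reports an averaged fetal heart rate; it does
not resolve individual cardiac cycles, so beat-to-beat variability — the
quantity obstetric HRV analysis actually needs — is lost. The Doppler signal
itself, however, contains one mechanical burst complex per cycle (valve
clicks and wall motion). `dusbeats` detects those cycles directly:

1. **Denoise** the raw 1 kHz signal: 15-level Haar decomposition, soft
   universal threshold per level (`σ·sqrt(2·ln N_level)`, σ from the finest
   detail MAD).
2. **Decompose** with ensemble EMD (EEMD) into intrinsic mode functions
   (IMFs), separating valve-scale from wall-scale oscillations.
3. **Scan** each informative IMF with the non-centered kurtosis ratio

   γ̂₄ = (N−1) · Σ x⁴(n) / (Σ x²(n))²

   over sliding windows of 50–600 ms (step 50 ms, shift 1 ms). γ̂₄ is large
   exactly where a window's energy is concentrated in a burst, ≈3 on
   Gaussian noise.
4. **Screen and select** (IMF, window) kurtosis vectors — a Chebyshev-style
   tail-mass screen rejects noise-like modes; selection either uses the
   preset optimal region (IMF levels 1–3, 300–400 ms windows) or, when
   reference beats exist, calibrates by minimising the beat-count mismatch
   and the beat-location variability over all cells.
5. **Detect beats** as peaks of the summed selected vectors under a 300 ms
   refractory constraint (fetal hearts stay below 200 bpm).

The package also provides the classical comparator (adaptive-window
autocorrelation of the signal envelope, `af_estimate()`), the evaluation
metrics used to compare estimators against reference RR intervals
(beat-count mismatch, successive beat error, `var_b_loc`, SDNN/RMSSD,
Bland–Altman), and a synthetic Doppler generator with known ground-truth
beats (`generate_rr_sequence()` + `synthesize_dus()`) so the entire pipeline
is testable without clinical data. See the methods vignette
(`vignettes/emd-kurtosis-methods.Rmd`) for the model, parameter rationale
and design notes.

## Worked example

```r
library(dusbeats)

# one-minute record at the early-gestation preset, 10 dB SNR
rr  <- generate_rr_sequence(mean_rr = 406.4, sdnn_target = 13.5,
                            rmssd_target = 9.5, n_beats = 150, seed = 1)
rec <- synthesize_dus(rr, snr_db = 10, jitter_sd = 5, seed = 2)
rec
#> <synthetic_record> 61.1 s @ 1000 Hz, 150 beats, nominal SNR 10 dB (measured 10.1 dB)

est <- estimate_fhr(rec$dus, fhr_config(ensemble_size = 10, max_imfs = 6, seed = 3))
evaluate_record(rec$true_beats, est)
#> <evaluation_report> mismatch -1.33% | successive beat error 12.95% | varB_loc 46.13 ms
#>   true: 150 beats (mean 407.6, SDNN 14.3, RMSSD 16.3 ms)
#>   est:  152 beats (mean 401.6, SDNN 65.0, RMSSD 101.3 ms)

af <- af_estimate(rec$dus)
evaluate_record(rec$true_beats, af)
#> <evaluation_report> mismatch 6.67% | successive beat error 3.76% | varB_loc 47.18 ms
#>   true: 150 beats (mean 407.6, SDNN 14.3, RMSSD 16.3 ms)
#>   est:  140 beats (mean 407.4, SDNN 13.2, RMSSD 11.2 ms)
```

Reading the reports: the EMD-kurtosis detector found 152 beats against 150
true ones (mismatch −1.33%; the sign flags over-detection) while the
autocorrelation baseline missed ten (mismatch +6.67%) — the beat-count
robustness contrast that motivates the method. Both mean intervals are
within a few ms of truth. The detector's estimated SDNN/RMSSD exceed the
true values — kurtosis beat-picking latches onto whichever mechanical event
dominates a cycle, inflating interval-to-interval differences — so its beat
count and mean rate are trustworthy well before short-term variability is;
the smoother baseline tracks individual intervals more tightly on the beats
it does find.

`tidy()`/`glance()` turn every result into tibbles, and `autoplot()` draws
signals, IMF stacks, interval tachograms and calibration surfaces.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/dusbeats.R simulate --mean-rr 406.4 --sdnn 13.5 --rmssd 9.5 \
    --n-beats 150 --snr-db 10 --seed 1 --format wav --out-prefix rec
Rscript inst/cli/dusbeats.R detect --input rec.wav --seed 1 --out beats.csv
Rscript inst/cli/dusbeats.R evaluate --truth rec_beats.csv --est beats.csv --out report.json
```

Subcommands: `simulate`, `detect`, `detect-af`, `calibrate` (emits the
mismatch/var_b_loc surface as CSV), `evaluate`. Every run writes a log with
the config hash and seed; identical config and seed give byte-identical
outputs.

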