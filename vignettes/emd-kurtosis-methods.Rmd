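---
title: "Estimating fetal beat-to-beat intervals from Doppler ultrasound: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating fetal beat-to-beat intervals from Doppler ultrasound: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dusbeats)
```

## The problem

Cardiotocography monitors the fetal heart with a continuous-wave Doppler
ultrasound (DUS) probe on the maternal abdomen. The probe returns the
mechanical signature of the heart -- wall motion and valve clicks -- rather
than its electrical activation, and commercial monitors reduce this signal to
an averaged heart rate. Beat-to-beat intervals, the substrate of heart-rate
variability (HRV) analysis, are much harder to recover: the signal is
non-stationary, the burst morphology drifts with the insonation angle, and
the mechanical events lag the electrical R wave by a delay that itself varies
from beat to beat.

`dusbeats` implements a time-domain detector for individual cardiac cycles in
DUS: empirical mode decomposition combined with a sliding non-centered
kurtosis statistic. It ships with an adaptive-autocorrelation baseline (the
classic approach to Doppler periodicity), the evaluation metrics used to
compare the two, and a synthetic DUS generator with known ground-truth beats
so that every part of the pipeline is testable without clinical recordings.

## The detector

The pipeline has five stages.

**1. Wavelet denoising.** The raw signal is decomposed to 15 levels with the
Haar basis; every detail level is soft-thresholded with the universal
threshold $\sigma\sqrt{2\ln N_j}$, where $N_j$ is that level's coefficient
count and $\sigma$ is the robust noise scale $\mathrm{median}(|d_1|)/0.6745$
estimated from the finest level. Broadband noise spreads evenly over detail
levels while cardiac energy concentrates in the coarser ones, so per-level
thresholds remove noise aggressively at fine scales and spare the signal. We
use symmetric (reflective) boundary extension: a periodic extension would
manufacture edge discontinuities that later masquerade as kurtosis peaks.
Note the aim is detection, not waveform restoration: soft thresholding
shrinks every surviving coefficient, so on nearly clean signals the denoised
waveform correlates marginally *less* with the noise-free component than the
input does -- the correlation gain becomes positive below roughly 0 dB SNR,
which is where denoising matters.

**2. Ensemble empirical mode decomposition.** EMD represents a signal as a
sum of intrinsic mode functions (IMFs): oscillatory components whose extrema
and zero-crossing counts agree to within one and whose local envelope mean is
zero. Each IMF is extracted by *sifting*: subtracting the mean of the
upper/lower cubic-spline extremal envelopes until the component is
well-behaved. Our stopping rule requires both the standard relative-change
criterion $\sum(h_{k-1}-h_k)^2 / \sum h_{k-1}^2 < 0.05$ *and* the
extrema/zero-crossing counting condition itself (checked on the full signal
and on the interior with 1% edge margins), capped at 100 iterations. The SD
criterion alone demonstrably leaves riding waves that violate the counting
condition; requiring both makes every returned mode a valid IMF at modest
extra cost. Envelopes are natural cubic splines through the extrema, with
the two outermost extrema on each side mirrored beyond the signal ends to
suppress endpoint swings. The ensembled variant (EEMD) averages the IMFs of
many runs on noise-perturbed copies of the signal (default: 100 members,
noise SD 0.2 of the signal SD), which breaks the mode-mixing that plain EMD
suffers on intermittent signals; the mode count is capped at the ensemble
minimum and surplus modes are folded into the residue so each member's
reconstruction is preserved. Sifting is implemented in C++; a one-minute
1 kHz record decomposes in well under a second per member.

**3. Sliding kurtosis.** For each IMF and each window width on a 50--600 ms
grid (step 50 ms), the non-centered kurtosis ratio

$$\hat\gamma_4 = \frac{(N-1)\sum_n x^4(n)}{\left(\sum_n x^2(n)\right)^2}$$

is computed at every 1 ms shift. This statistic is scale-invariant and large
exactly when the window's energy is concentrated in a few samples -- a
Doppler burst -- and near 3 for Gaussian noise. An all-zero window is defined
to have kurtosis 0 so silent segments can never rank as peaks. Each value is
time-stamped at the window *center*, aligning kurtosis peaks with burst
centers; the cumulative-sum implementation makes a whole vector O(n).

**4. Screening and selection.** IMFs are screened with a Chebyshev-style
tail-mass test: a vector passes when the fraction of samples beyond
$\lambda$ sample standard deviations from the mean exceeds
$0.1/\lambda^2$, a one-tenth share of the Chebyshev bound. We apply it to
the IMF amplitude vector: a burst-carrying mode is amplitude-sparse and
heavy-tailed (which is precisely what high kurtosis means), while a
noise-dominated mode is not. With the default $\lambda = 3.5$ the cap is
0.82%; Gaussian noise (tail mass $\approx$ 0.05% at 3.5 SD) fails by an
order of magnitude and burst modes pass by one. We chose $\lambda = 3.5$
rather than the conventional 2 because at $\lambda = 2$ the Gaussian tail
mass (4.55%) already exceeds the scaled bound (2.5%), so the test could not
reject plain noise at all. The screen makes noise-only input fail loudly
(`no IMF passed`) instead of fabricating a regular beat train.

Vector selection then has two modes. In *calibrated* mode, ground-truth
beats (from a simultaneously recorded fetal ECG in the clinical setting, or
from the generator here) are available: each (IMF, window) cell is evaluated
on its own by detecting beats from that single vector and scoring the
absolute beat-count mismatch together with the beat-location variability
`var_b_loc`; both objectives are rank-normalized across cells and the lowest
decile of the summed ranks is selected. Rank normalization is our
aggregation choice for "minimize both": it is scale-free, so a percentage
and a millisecond quantity can be summed without tuning weights. In
*default* mode -- deployment, no truth available -- the preset optimal region
is used: IMF levels 1--3 with 300--400 ms windows, the region where
calibration surfaces bottom out for fetal records whose mean RR sits just
above the window size.

**5. Peak detection.** The selected kurtosis vectors are summed on their
common center-time grid (vectors of different window widths cover slightly
different spans; the sum is trimmed to the intersection) and local maxima are
accepted greedily by descending height, suppressing any candidate within
300 ms of an accepted peak. The 300 ms refractory distance is physiological
-- fetal hearts do not beat above 200 bpm -- and guarantees every returned
interval is at least 300 ms. Ties are broken by position, making detection
fully deterministic.

## The autocorrelation baseline

The comparator is a simplified, faithful-in-spirit reimplementation of the
adaptive-window autocorrelation approach: the envelope (magnitude of the
analytic signal, low-pass smoothed at 30 Hz) is scanned by a window that
advances by the last accepted period; each step takes three staggered
periodicity measurements (lag of the normalized autocorrelation maximum
within 250--800 ms, i.e. 75--240 bpm, refined to sub-sample precision by
parabolic interpolation through the peak) and aggregates them by median; the
window size tracks three times the running-mean period. One detail matters:
a 3-cycle window cannot support an 800 ms lag search when the rhythm is
fast, so the searched lag range is capped at just under half the current
window -- with a 3-cycle window the cap is 1.5 cycles, which always covers
the true period. A window counts as unreliable when its best normalized
autocorrelation peak is weak; the single-window operation
(`af_periodicity()`) uses 0.1, while the estimator applies 0.25 because the
30 Hz envelope smoothing leaves enough short-range sample correlation to
push pure-noise autocorrelations to ~0.2. If more than half the steps are
unreliable, the record is rejected as too noisy.
It is a baseline, not a reference implementation of any specific clinical
algorithm: autocorrelation pools all beats inside the window, so it smooths
variability and responds slowly to rate changes, which is exactly the
behaviour the EMD-kurtosis method is designed to beat.

## Evaluation metrics

* **Mismatch error** (signed %): $100\,(n_{true} - n_{est})/n_{true}$;
  negative means over-detection. Cohorts aggregate it as root mean square --
  the only aggregation that gives one unsigned number per group while
  penalising over- and under-detection symmetrically.
* **Successive beat error** (%): mean of
  $100\,|RR_{true}(i) - BB_{est}(i)|/RR_{true}(i)$ over the first
  $N_{min}$ index-paired intervals. Index pairing is the definitional
  choice; it means one missed beat shifts every later pair, so
  `evaluate_record()` also logs a clearly-marked time-aligned diagnostic
  variant that matches beats before differencing.
* **var_b_loc** (ms): each estimated beat is greedily matched to its nearest
  unused true beat (offsets capped at 300 ms) and the sample SD of the
  absolute offsets is returned. A constant detection latency -- for example
  the electromechanical delay, or the window-center stamping offset -- does
  not contribute by construction; only the beat-to-beat spread counts.
* **HRV summaries**: mean interval, SDNN (sample SD, $n-1$ denominator; the
  definitional sources do not fix the denominator, we use the unbiased
  sample form), RMSSD (root mean square of successive differences).
* **Bland--Altman**: mean difference and mean $\pm 2$ SD limits of
  agreement of paired true/estimated measures.

## The synthetic generator

`generate_rr_sequence()` draws RR intervals as mean plus a stationary AR(1)
deviation process. The lag-1 coefficient is solved in closed form from the
two variability targets, $\varphi = 1 - \mathrm{RMSSD}^2/(2\,\mathrm{SDNN}^2)$,
which gives independent control of the marginal SD and the
successive-difference SD; RMSSD $> 2\,$SDNN is rejected as unreachable by
any stationary process. Preset targets mirror healthy mid-gestation fetal
physiology (mean RR 400--420 ms, SDNN 10--17 ms, RMSSD ~10 ms); intervals
are clamped to 250--800 ms (75--240 bpm).

`synthesize_dus()` renders each cardiac cycle as three Gaussian-windowed
tone bursts plus a continuous clutter floor:

| component | carrier | width | position | mean amplitude |
|---|---|---|---|---|
| systolic valve click (S1) | 80 Hz | 30 ms | beat time | 1.0 |
| wall motion | 25 Hz | 180 ms | +90 ms | 0.8 |
| diastolic valve click (S2) | 60 Hz | 35 ms | +0.55 cycle | 0.9 |
| tissue clutter | 15--100 Hz band | continuous | everywhere | 0.15 of burst RMS |

Real fetal DUS audio shows both a systolic and a diastolic click group
(valve openings and closures) over sustained lower-frequency wall motion,
with continuous backscatter between beats; a first draft of this generator
with a single 80 ms wall burst and digital silence between cycles turned out
to be a poor emulator -- perfectly clean, perfectly repetitive bursts against
true silence make tiny analysis windows artificially ideal, because the
scale-invariant kurtosis locks losslessly onto a lone clean click or even
onto the first samples of a burst rising out of exact zeroes. The frozen
model therefore includes sustained wall motion, the S2 click, per-beat
lognormal amplitude (CV 0.35) and width (CV 0.25) variation, 10 ms SD jitter
of the wall offset, and the clutter floor. Beat times get zero-mean Gaussian
jitter (default SD 5 ms, clamped to preserve ordering), modelling the
beat-to-beat variability of the electromechanical delay. White Gaussian
noise is added so that the burst-power-to-noise-power ratio *on the
burst-support samples* equals the requested SNR; defining SNR on burst
support keeps the number meaningful -- inter-burst quiet would otherwise
deflate it by several dB.

**What the generator does not emulate.** Probe re-orientation and fetal
movement episodes (minute-scale nonstationarity), maternal ECG or muscle
contamination, non-Gaussian impulsive artifacts, hardware filtering, and the
true acoustic morphology of Doppler reflections. Passing tests on this
family shows the algorithm chain is correct and robust to the modelled
variability; it does not certify clinical accuracy. One concrete consequence
shows up in the calibrated window sweep: on these records the objective
surface has the expected local minimum at 300--350 ms windows, but windows
around 150 ms -- wide enough to hold one click complex of this generator --
remain competitive or better, whereas on clinical data windows just below
the mean RR are reported to win outright. The corresponding window-optimum
check in the acceptance suite measures exactly this and is expected to fail
on the synthetic family; we kept the check at the clinical expectation
rather than adapting it to the generator.

## Numerical choices and degenerate inputs

* Kurtosis of an all-zero window is 0 (silence must not rank as a peak);
  negative rounding residue in the cumulative sums is clamped at 0.
* Peak search breaks ties by position; detection and both estimators are
  fully deterministic given the configuration seed.
* EEMD derives all member noise from one seeded stream, so results are
  bit-reproducible; `ensemble_size = 1` with zero noise is exactly `emd()`.
* A signal shorter than $2^{15}$ samples reduces the wavelet depth to
  $\lfloor \log_2 n \rfloor$ with a warning rather than failing.
* `var_b_loc` of a single matched pair is 0 (no spread measurable); no
  matched pair within 300 ms is an error.
* Noise-only input errors at the screening stage (`dusbeats_no_imf`);
  the detector never invents a beat train at the refractory distance.

## Problem sizes in the test suite

The unit and acceptance tests run the full pipeline on one-minute
equivalent records (150 beats, 1 kHz) with an EEMD ensemble of 10 members
and at most 6 modes -- our standard test-scale configuration, chosen because
the beat-scale structure lives in the first few modes and a 10-member
ensemble already suppresses mode mixing on these records; the package
default remains 100 members. Stochastic properties use 10--20 seeded
records per check.

## Known limitations

* The estimated SDNN/RMSSD overestimate the true interval variability
  substantially (the detector picks whichever mechanical event dominates a
  cycle, and event-to-event hopping inflates successive differences); the
  mean interval and beat count are accurate. This direction -- accurate
  mean, inflated variability -- is the expected behaviour of kurtosis-based
  beat pickers on mechanical signals.
* Batch processing of ~1-minute records only; no streaming mode.
* The Chebyshev screen's operating point (lambda 3.5, selectivity 0.1) was
  chosen on the synthetic family; very different burst statistics may need
  the exported knobs.
* `eemd()` averages aligned modes by index; signals whose members disagree
  wildly in mode count lose detail to the residue fold-in.
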