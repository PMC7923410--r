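---
title: "Estimating 24-hour HRV (SDNN24) from semi-continuous wearable heart-rate data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating 24-hour HRV (SDNN24) from semi-continuous wearable heart-rate data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wearhrv)
```

## The problem

SDNN24 — the standard deviation of all normal-to-normal (NN) inter-beat
intervals over 24 hours — is the gold-standard global heart-rate-variability
metric: values above 100 ms indicate healthy cardiac autonomic function,
50–100 ms compromised function, and below 50 ms substantially elevated
mortality risk. Computing it requires a continuous beat-to-beat recording
(traditionally a Holter ECG). Wrist-worn wearables do not provide that:
photoplethysmography (PPG) beat detection is too noisy, so devices report
only the *average heart rate* over windows of one to sixty minutes.

Window-averaging is a low-pass filter. The standard deviation of the windowed
series (SDANN-type estimators) therefore misses all spectral content above
roughly `1/(60·w)` Hz for a `w`-minute window and systematically
*underestimates* SDNN24. The saving grace is the shape of the human HRV
spectrum: sinoatrial-node dynamics give it a `1/f` profile, so the ultra-low
(ULF, periods 5 min–24 h) and very-low (VLF, 25 s–5 min) frequency bands
carry most of the total power, and those bands survive the filter. This
package implements the resulting estimation pipeline:

1. windowed time-domain estimators (SDNN24, SDNNi24, SDANN24, SDANNHR24)
   with a calibrated PPG noise model;
2. Lomb–Scargle spectral analysis of the unevenly sampled NN series and two
   corrections that add back the filtered-out power using an *a-priori*
   reference spectrum built on a separate cohort;
3. a fixed-period cosinor model of the circadian HR rhythm (MESOR,
   amplitude, acrophase), whose parameters, together with SDANNHR24, feed
   cardiovascular-risk classifiers;
4. a synthetic 24-h beat-series generator that reproduces the statistical
   structure the method relies on, so every claim above is testable without
   clinical data.

## Conventions and units

Timestamps are seconds from record start; NN intervals milliseconds; heart
rate bpm; spectral power ms²; frequency Hz. All time-domain standard
deviations use the population convention (divisor *N*), matching the
estimator definitions; a `sample = TRUE` flag switches to *N − 1*.
Windows tile the record as half-open intervals from `origin` (default 0);
windows with NN-interval coverage below `min_coverage` (default 0.5) are
dropped. Estimators with 24-h semantics check a configurable minimum span
(default 20 h).

## Preprocessing

Beat annotations carry outliers and ectopic beats. The cleaning rule is the
field's de-facto standard: a range filter (NN outside [300, 2000] ms) plus
the Malik 20% relative-difference rule against the *previous clean beat*,
both configurable via `preprocess_config()`. Two guards make the sequential
rule robust:

* **Reference rescue.** An ectopic that slips under the threshold (because
  the reference happened to sit high) would otherwise become the reference
  and trigger a cascade of false flags. When a beat disagrees with the
  reference but agrees with the clean beat before it, *and* the next beat
  confirms the new level, the reference itself is flagged retroactively.
* **Staleness resync.** After three consecutive flags against the same
  reference the rule re-anchors on the current beat, so a corrupt leading
  beat cannot poison the record.

Flagged beats are reconstructed by a least-squares quadratic in the beat
*timestamp* through the two clean beats on each side (four support points).
Flagged runs spanning more than `max_gap_s` (default 10 s) are dropped as
honest gaps rather than fabricated. Timestamps are then rebuilt by one
monotone cumulative pass in which consecutive beats advance by their NN
interval while true recording gaps keep their original wall-clock duration.

On synthetic records with 2.5% injected ectopics the pipeline flags ≈2.5%
of beats and recovers the ground-truth SDNN24 to well under 1%.

## Spectral analysis and the window-loss corrections

Because beats sample time unevenly, the power spectral density is estimated
with the Lomb–Scargle periodogram (implemented in C++; `lomb_scargle_psd()`).
The density obeys a *variance normalisation*: its integral over the
evaluated band approximates the time-domain NN variance in ms², making
"total spectral power" and "SDNN24²" interchangeable. The default grid is
log-spaced with 2000 points from `1/span` to 0.5 Hz — a `1/f`-shaped
spectrum spans more than four decades and a linear grid would under-resolve
the ULF region. Band powers (`band_powers()`) integrate the density over the
operative band definitions: ULF 5 min–24 h, VLF 25 s–5 min, LF 7–25 s, HF
2–7 s.

`build_apriori_spectrum()` averages per-subject densities on a common grid.
Two numerical choices matter and are deliberate:

* the grid starts at `1/(2·span)` so the spectral line of the circadian
  oscillation (width ≈ `1/span`, centred at 1/86400 Hz) is integrated in
  full rather than cut in half at the grid edge;
* the reference *total* power is the cohort mean of the time-domain
  variances (Parseval-exact), not the grid integral: near-sinusoidal LF/HF
  oscillations produce spectral lines far narrower than any practical grid
  spacing, and their power must still be counted in the total that the
  corrections redistribute. The grid integral is retained as
  `grid_total_ms2`; the two agree within the normalisation tolerance.

Two corrections then map a windowed variance back to SDNN24:

* `adj_mean()` **adds** the a-priori power above the window's cutoff
  frequency `1/(60·w)` — one fixed number per window, identical for every
  subject.
* `adj_w()` **rescales** the measured variance by the ratio of a-priori
  total power to the power the windowed measurement retains, i.e. it assumes
  the missing high-frequency power is proportional to the measured
  low-frequency power. By default the retained power is computed through the
  boxcar window's actual frequency response,
  `∫ S(f)·sinc²(πfw) df` (`transfer = "sinc"`): a window mean does not cut
  the spectrum off sharply at `1/(60·w)` but attenuates frequencies below it
  (≈60% power loss already at half the cutoff) and leaks sidelobe power from
  above it. An idealised brick-wall variant (`transfer = "sharp"`, the ratio
  `1 + P_high/P_low` at the cutoff) is kept for reference; it leaves a
  systematic residual underestimate at short windows precisely because it
  cannot see the sub-cutoff attenuation.

On 30-subject synthetic cohorts sharing the a-priori spectral shape, the
default `adj_w` shrinks the mean bias from ≈ −12 ms (uncorrected, 1-min
windows) and ≈ −30 ms (60-min) to within a few ms, with the residual error
growing with window length — the longer the window, the larger the
correction factor and the more estimation noise it amplifies.

## Circadian rhythm

`fit_cosinor()` fits `HR(t) = M + A·cos(2π(t/T + φ)) + ε` at a fixed 24-h
period by the standard linearisation (cosine and sine regressors), returning
the MESOR `M`, amplitude `A ≥ 0` and acrophase `φ ∈ [0, 1)` in cycles
(also reported as the hour of peak HR). Additional harmonics (e.g. 12 h) can
be requested; their amplitudes are reported but the downstream features use
only the fundamental, since only `M` and `A` feed the risk models. The fit
runs on segment-level HR (default 5-min windows) — the view an HR-only
wearable actually provides.

## Risk classification

NYHA heart-failure classes 0–1 map to low cardiovascular risk, 2–4 to high
(`label_risk()`). `train_classifier()` fits, on a stratified 70/30 split
with features z-scored on the training split: logistic regressions on
SDNN24 alone, on SDANNHR24 alone, or on the HR feature triple
(SDANNHR24, MESOR, amplitude); a random forest; and a single-hidden-layer
neural network with leaky-ReLU activation and dropout, tuned by random
search (≤400 draws over 1–8 hidden units, slope 0–1, dropout 0–0.99, batch
size 1–32) on a stratified 80/20 train/validation split of the training
data. Baselines: `b1` guesses from the training class distribution, `b2`
always predicts the majority class (its minority-class precision, recall
and F1 are exactly zero — the floor any useful model must clear). All
reports carry per-class precision/recall/F1 on the held-out 30% and are
deterministic given the split seed.

Two published fixed-coefficient predictors are frozen as reference
functions: a linear SDNN24 predictor from SDANNHR24 and MESOR
(`predict_sdnn24_fixed()`; the magnitude of the SDANNHR24 coefficient is
only dimensionally coherent with SDANNHR24 in *seconds*, so the function
takes seconds in and returns ms) and a logistic high-risk score
(`predict_risk_fixed()`; coefficient magnitudes ≈0.2–0.3 indicate z-scored
inputs, which is what the function expects).

## The synthetic generator

`generate_beats()` builds the instantaneous NN process on a 1-s grid as
mean + 24-h cosine + band-limited `1/f^α` noise (1/86400–0.04 Hz) + LF and
HF sinusoids, then emits beats by integrate-and-fire (each beat advances
time by the local NN interval, so timestamp/interval consistency holds by
construction), and finally injects ectopics (±25–60% perturbations) and
recording gaps. The clean pre-corruption series is always returned as
ground truth. Defaults describe a healthy adult: mean NN 850 ms, circadian
amplitude 130 ms, 9500 ms² of 1/f power, 50/35 ms LF/HF tones, 2.5%
ectopics, ~0.5 gaps/h of 60 s — SDNN ≈ 141 ms with >70% of power in ULF.

Two stabilising choices, made once:

* the `1/f` band excludes the FFT bin at the circadian fundamental — that
  line belongs to the deterministic cosine, and a stochastic component at
  the same frequency would covary with it realisation-by-realisation,
  scattering the realised SDNN by ±30% around its analytic value;
* the zero-mean deviation is rescaled so the grid variance equals the
  analytic component sum exactly (variance targeting), making the realised
  beat-level SDNN match the analytic target within ~2–3%.

`generate_cohort()` draws per-subject SDNN24 targets from the published
group distributions — low risk N(142.14, 31.05) ms, high risk
N(86.54, 43.29) ms, truncated to physiological ranges — and rescales the
profile components to hit them; high-risk subjects additionally run a
shorter mean NN (faster resting HR). `simulate_feature_cohort()` draws
feature rows directly from those group statistics (with SDANNHR24
correlated at r = 0.93, and MESOR/amplitude calibrated to typical circadian
values: 72 ± 8 vs 80 ± 10 bpm MESOR, 8 ± 3 vs 5 ± 2.5 bpm amplitude —
heart-failure patients run higher resting HR with a blunted circadian
swing); it is the fixture for classifier comparisons, where the feature
distributions rather than the beat stream carry the signal.

What the generator does *not* emulate: respiratory modulation beyond the HF
tone, activity bouts, posture changes, broadband LF/HF content, or
device-specific PPG artefact structure beyond the windowed Gaussian HR
error. Passing tests therefore demonstrate correctness of the estimators
and corrections under the stated spectral model, not clinical performance
on any particular device.

## Numerical choices and degenerate inputs

* Lomb–Scargle: classic Scargle tau-offset form; constant series yield a
  zero spectrum; fewer than 16 beats is an error.
* PPG noise: Gaussian error is injected on the HR scale (what the device
  reports) and mapped back through `60000/HR`; the tabulated error SDs
  (5.91, 5.09, 4.71, 4.01, 3.95 bpm at 1/5/10/30/60 min) are log-linearly
  interpolated between windows and clamped outside; the tabulated mean bias
  is exposed but not added by default, since the error model is zero-mean.
* Cosinor: rank-deficient designs (all samples at one phase) and spans
  under half a period are errors; acrophase ties are resolved by `atan2`.
* t-tests: pooled-variance Student's t by default (Welch optional); the
  group t-score is `(mean_a − mean_b)/SE`, so passing the low-risk group
  first makes healthier-higher positive.
* Classifier metrics: 0/0 precision or recall is reported as 0 (the `b2`
  minority row), never NaN.
* Problem sizes in the test-suite and acceptance runs: single 24-h subjects
  for spectral checks; 10-subject a-priori plus 30-subject evaluation
  cohorts for the corrections; 40–100 feature-cohort replicates for the
  classifier comparisons. These sizes give stable means while keeping a
  complete run in the minutes range.

## Known limitations

* The a-priori corrections assume the target cohort shares the reference
  cohort's spectral *shape*; systematic shape differences (e.g. correcting
  heart-failure subjects with a healthy-cohort spectrum) bias `adj_w`
  proportionally.
* `adj_mean`'s fixed additive term overestimates SDNN24 for low-variance
  subjects, increasingly so at long windows — visible in its +15 ms mean
  bias at 60-min windows on mixed cohorts; this is a property of the
  correction, not a defect of the implementation.
* The NN classifier is a deliberately small network appropriate for
  cohort sizes in the tens; it is tuned by random search, not Bayesian
  optimisation.
* Single-column RR files reconstruct timestamps by cumulative sum and so
  cannot represent recording gaps distinguishably from long NN intervals;
  two-column files do.
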