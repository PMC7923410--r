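# wearhrv

Estimation of the 24-hour heart-rate-variability metric **SDNN24** from the
semi-continuous, window-averaged heart-rate (HR) measures that wrist-worn
wearables actually report — for researchers in digital cardiology and
biostatistics who want Holter-grade HRV summaries from PPG fitness-tracker
data, and a fully synthetic test bed to validate the pipeline on.

## The method

SDNN24 is the population standard deviation of all normal-to-normal (NN)
inter-beat intervals over 24 h,

    SDNN24 = sqrt( Σᵢ (NNᵢ − N̄N)² / N ),

and equals the square root of the total power of the HRV spectrum. Wearables
report only windowed mean HR, so the reachable estimator is

    SDANNHR24 = population SD over windows of ANNⱼ,   ANNⱼ = 60000 / (HRⱼ + εⱼ),

with εⱼ a zero-mean Gaussian measurement error whose SD is calibrated per
window length (5.91 bpm at 1 min down to 3.95 bpm at 60 min). Window
averaging low-passes the signal at ~1/(60·w) Hz, so SDANNHR24 underestimates
SDNN24 by the missing high-frequency power. Because the human HRV spectrum is
1/f-shaped (ULF/VLF dominate), the loss is modest and correctable: with an
a-priori reference spectrum S(f) built on a separate cohort,

* **adjMean** adds the reference power above the cutoff:
  `sqrt(VAR(ANN) + P_apriori(f > 1/(60·w)))`;
* **adjW** rescales by the reference total-to-retained ratio:
  `sqrt(VAR(ANN) · P_total / P_retained(w))`, where by default
  `P_retained = ∫ S(f)·sinc²(πfw) df` is the power the boxcar window mean
  actually passes (an ideal-cutoff variant is available).

A fixed-period cosinor fit `HR(t) = M + A·cos(2π(t/T + φ)) + ε` (T = 24 h)
summarises the circadian rhythm; (SDANNHR24, MESOR M, amplitude A) feed
logistic-regression / random-forest / small neural-network classifiers of
cardiovascular risk (NYHA class 2–4 vs 0–1), benchmarked against
distribution-matched and majority-class baselines.

All of this is exercised end-to-end on a synthetic generator that emits 24-h
beat series with circadian, 1/f, LF/HF, ectopic-beat and gap structure, and
returns the clean series as ground truth. See the vignette
(`vignettes/estimating-sdnn24-from-wearable-hr.Rmd`) for the model details
and design choices.

## Worked example

```r
library(wearhrv)

g <- generate_beats(generator_profile(seed = 7))   # corrupted + clean truth
g
#> <synthetic_beats> 103973 beats (2558 ectopic, 721 dropped in gaps);
#>   analytic SDNN 140.8 ms, realised (clean) 144.3 ms

res <- preprocess(g$series)                        # flag + repair
res$report
#> <preprocess_report> 103973 beats: 67 outlier, 2481 ectopic (2.45% flagged);
#>   2546 interpolated, 2 dropped

est <- sdnn_estimates(res$series, window_min = 5)  # noiseless wearable view
est
#>  sdnn24_ms sdnni24_ms sdann24_ms sdannhr24_ms window_min n_segments
#>   144.3657   82.04734   115.3447     115.3447          5        288

classify_sdnn(est$sdnn24_ms)
#> [1] healthy

# correct the windowing loss with a reference spectrum from another cohort
ap <- build_apriori_spectrum(
  lapply(generate_cohort(3, 3, seed = 99), function(r) attr(r, "clean")))
adj_w(est$sdannhr24_ms^2, 5, ap)
#> [1] 141.1555        # vs ground-truth SDNN24 = 144.27 ms

cosinor_from_segments(segment_hr(res$series, 5))
#> <cosinor_fit> MESOR 72.72 bpm, amplitude 11.85 bpm, acrophase 0.497 cycles
#>   (peak at 12.06 h), residual SD 6.74 bpm (n=288, T=24 h)
```

Reading the numbers: the 5-min windowed estimator (115.3 ms) under-reads the
true SDNN24 (144.3 ms) by the spectral power the window average filters out;
the a-priori `adj_w` correction recovers 141.2 ms, within ~2%. The preprocess
report shows the injected 2.5% ectopic beats being flagged and repaired, and
the cosinor fit recovers the circadian HR rhythm of this subject.

With wearable measurement noise (`sdnn_estimates(..., noise_sigma_bpm =
ppg_noise_sigma(5), seed = 7)`) SDANNHR24 rises to 127.0 ms — the injected HR
error adds variance of its own, which is why noise and windowing are modelled
separately.

A thin command-line front end over the same functions ships in
`inst/cli/sdnn.R` (subcommands `simulate`, `simulate-cohort`, `compute`,
`spectrum`, `apriori`, `cosinor`, `features`, `classify`, `validate`,
`pipeline`).

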