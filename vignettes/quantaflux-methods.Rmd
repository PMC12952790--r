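---
title: "Models and methods behind quantaflux"
author: "quantaflux authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind quantaflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quantaflux)
```

## What the package computes

quantaflux analyzes single-ROI fluorescence time series from calcium-imaging
experiments at synapses: spontaneous quantal ("mini") transients reported by
genetically encoded calcium indicators such as GCaMP, and evoked transients
time-locked to electrical stimulation. The pipeline is

1. **Normalization** — raw intensity F(t) to ΔF/F(t), or the two-channel
   ratio R(t) = F~sig~(t)/F~ref~(t) to ΔR/R(t);
2. **Detection** — local-maximum candidates filtered by amplitude threshold,
   width at half height, and minimum inter-peak distance;
3. **Kinetics** — exponential rise and decay time constants per event by
   Levenberg–Marquardt least squares;
4. **Protocol analysis** — assignment of events to stimulation-frequency
   blocks and train summaries (facilitation index, post-train decay);
5. **Paired statistics** — matching optical events to simultaneously
   recorded miniature postsynaptic potentials, detection fraction, amplitude
   correlation, pairwise active-zone (AZ) tests, and IQR outlier flagging.

A seeded synthetic-recording generator with ground truth underlies every
validation claim the test suite makes.

## Baseline estimation and normalization

The resting fluorescence of an indicator drifts slowly (photobleaching,
focus drift), so ΔF/F uses a *time-varying* baseline F₀(t): at each frame a
centered window (default 101 frames, i.e. 50 frames on each side) is taken,
truncated at the trace ends, and a summary of the window values is computed:

* **percentile** (default, 30th): the linear-interpolation percentile, the
  value at sorted position p/100·(m−1) (0-based) of the m window values.
  This is the common "linear" percentile definition (R's `quantile`
  type 7); the convention matters at these window sizes and is therefore
  fixed and documented.
* **lowest fraction** (default 10%): the mean of the ⌈0.10·m⌉ smallest
  window values. This is the default for ratiometric baselines R₀(t), where
  the quiescent ratio is the meaningful floor. We read "the lowest 10% of
  values" as a set average rather than a quantile; the 10th percentile is
  available by switching methods.

Windows truncate at the ends rather than padding or reflecting — padding
fabricates data, and the truncated estimate remains a valid window summary.
Then ΔF/F(t) = [F(t) − F₀(t)]/F₀(t), and for dual-channel recordings
ΔR/R(t) = [R(t) − R₀(t)]/R₀(t) with the reference optionally smoothed by a
centered moving average *before* division (smoothing after division would
also smooth the signal of interest). Because the sliding percentile of a
noisy flat trace sits slightly below the mean (the 30th percentile of
symmetric noise), normalized traces carry a small positive offset of about
0.5 σ; this is inherent to percentile baselining and is one reason the
detection layer can smooth before thresholding (below).

Two benchmark-style operations bypass the sliding baseline: a **linear
bleach correction** that regresses the mean intensity of a short window
(default 100 ms) before each low-frequency stimulus on the window-center
time and subtracts the fitted line (anchored at the first window, so its
mean is unchanged; a divide-by-line variant is available since an additive
and a multiplicative reading are both defensible), and a **rest
normalization** that uses a single constant baseline, the mean over the
100 ms preceding the first stimulus (half-open window: a frame exactly at
the stimulus time is excluded).

## Event detection

Candidate peaks are strict local maxima (a plateau counts once, at its first
frame). Three criteria filter them:

* `threshold` — minimum peak value in normalized units;
* `minWidth` — the trace must stay above half the peak's own height for at
  least this many contiguous frames around the peak; chosen as
  *relative*-height width because an absolute criterion would conflate
  amplitude and width;
* `minDistance` — among peaks closer than this (ms), the larger is kept,
  ties going to the earlier peak. Suppression is greedy in descending
  amplitude, the standard non-maximum-suppression order, which makes the
  result deterministic and (empirically, property-tested) monotone: raising
  the threshold or the distance never yields more events.

`detectionSettings(smoothWindow=)` optionally applies a centered moving
average before candidate search. For near-threshold minis this is decisive:
at amplitude 5 σ and threshold 3 σ, unsmoothed single-frame thresholding
both misses events and accepts noise spikes, while a 5-frame window at
100 fps raises the effective SNR by ≈√5 and brings the operating point to
≈97% sensitivity with ≈0% false positives (see the acceptance suite). The
default is off, because smoothing also widens merged events; amplitudes of
detected events are then measured on the smoothed series so that the
reported value describes the waveform that was detected.

Manual rescue (`nearestPeak`) returns the local maximum nearest a given
time within a search radius, *ignoring* the threshold — its purpose is to
recover events the automatic pass missed — with exact distance ties going
to the earlier peak.

## Kinetics

**Decay.** From the peak onward, y(t) = y~peak~·e^(−t/τ~decay~) is fitted by
Levenberg–Marquardt (via minpack.lm) with the amplitude free, initialized
from the log-linear closed form. The default fit span runs until the trace
first drops below 10% of the peak, capped at 1000 ms. Segments whose
log-linear slope is not negative are flagged non-decaying
(`converged = FALSE`) rather than fitted. The LM contract uses an iteration
cap of 200 and a relative-change tolerance of 1e-8; on noiseless
exponentials the fit agrees with the closed form to <0.1% regardless of
initialization, and it is scale-equivariant.

**Rise.** The onset is the last pre-peak frame at or below 10% of the peak
(the fraction is a parameter). Over [onset, peak] the saturating model
y(t) = A·(1 − e^(−(t−t₀)/τ~rise~)) is fitted with A, τ and t₀ free. Two
sampling realities shape the implementation:

* The *sampled* argmax can fall past the true peak, on the early decay;
  feeding that sample to a saturating model biases τ~rise~ low by tens of
  percent. With at least 4 samples the fit therefore uses a change-point
  model — saturating rise up to a free peak time inside the last frame
  interval, multiplied by the event's exponential decay (constant taken
  from the decay fit) beyond it. At 100 fps and SNR 10 this moves the
  median error for a 14 ms rise / 67 ms decay transient from −27% to
  within a few percent.
* A rise spanning fewer than three frame intervals carries essentially no
  curvature information. Such events are flagged `"unresolved rise"`
  (`converged = FALSE`) and τ~rise~ is reported as half a frame interval —
  the midpoint of the feasible interval (0, Δt], a bounded point estimate
  rather than a fit. At 100 fps this is the typical outcome for rise
  constants at or below ~14 ms paired with fast decays; rise kinetics at
  these frame rates are sampling-limited, and the diagnostics say so
  per event.

**Benchmark (rate) form.** `fitDecayRateForm` fits ΔF/F = A₀·e^(bt) with t
in seconds and reports the intercept A₀ and τ = 1000/(−b) ms, the
convention used when averaging aligned single-stimulus sweeps.
`alignAndAverage` shifts each sweep so its first supra-threshold frame
(default threshold: twice the pre-stimulus SD) sits half a sampling
interval after the stimulus — 1.6475 ms at Δt = 3.295 ms — then averages
over the common overlap, excluding (with a warning) sweeps that never cross
threshold.

## Stimulation protocols and trains

A protocol is an ordered set of labeled frequency blocks; block times must
be strictly increasing and consistent with 1000/frequency within a 5%
tolerance (stimulus clocks are often quantized to the frame clock).
`partitionEvents` labels each event with the block of the nearest preceding
stimulus when the latency lies in (0, 100 ms] (window configurable), at
most one event per stimulus (nearest latency wins; the rest stay
unassigned). Labeling is idempotent.

`trainSummary` measures first and final train responses *from the pre-train
baseline* (mean over 100 ms before the first stimulus), searching one
inter-stimulus interval after the first and last stimulus; the facilitation
index is final/first, and the post-train decay constant comes from a decay
fit over 1 s after the final peak. Measuring from baseline matches the
field's reporting convention but includes the pedestal of unrelaxed earlier
responses: for a decay constant τ and inter-stimulus interval T the
pedestal is ≈ e^(−T/τ)/(1 − e^(−T/τ)) of a unit response, i.e. ≈0.9% at
τ = T/4.7 but ≈45% at τ = T. The validation trains therefore use τ well
below T (9 ms vs 46.95 ms at 21.3 Hz), where gain ratios are recovered
within ~1%, and the test sampling grid is chosen commensurate with the
train (frame rate 47 × 21.3 Hz) so every stimulus is sampled at the same
phase and sampling error cancels in the final/first ratio. A
trough-relative amplitude mode is available for heavily summating trains.

## Paired optical–electrophysiology statistics

`matchEvents` pairs optical transients with miniature postsynaptic events
by greedy globally-nearest matching: repeatedly accept the unpaired
cross-modal pair with the smallest |Δt| ≤ tolerance (default 50 ms), ties
toward the earlier event. The rule is deterministic, order-invariant, and
conserves counts. From a match: the detection fraction (pairs / ephys
events) and the Pearson correlation of paired amplitudes with r² and n.

`azPairwiseTests` runs a paired two-tailed t-test for every pair of active
zones, paired by stimulus number, and reports the fraction significant at
α = 0.05 with the full p-value matrix. The t statistics are computed in
closed form from the per-AZ means and the cross-AZ covariance matrix —
algebraically identical to `t.test(paired = TRUE)` (the test suite checks
every p against it) — which keeps thousand-replicate calibrations fast.
Pairs with zero-variance differences have no defined statistic and are
excluded, with the count reported. No multiple-testing correction is
applied by default (raw fractions are the reported quantity); Bonferroni or
BH can be switched on. `iqrFlags` pools all individual responses across
AZs, computes Q1/Q3 with the same linear-interpolation convention as the
baseline percentile (internal consistency), and flags AZs whose mean lies
outside [Q1, Q3]. Distribution comparisons use the two-sample
Kolmogorov–Smirnov test with the asymptotic two-sided p value.

## The synthetic generator

`simSpec` + the `simulate*` functions produce every fixture used in
validation, all bit-reproducible under a seed:

* **Transient kernel**: unit peak, saturating exponential rise up to the
  peak time t\* = τ~r~·log(1 + τ~d~/τ~r~), pure exponential decay beyond
  it. The kernel is deliberately the exact model family the rise and decay
  estimators fit, so "ground truth" for τ~rise~ and τ~decay~ is well
  defined; the price is a derivative kink at the peak that real indicator
  transients do not have. A smooth kernel (e.g. a product of rise and
  decay terms) makes the single-exponential decay fit overestimate τ by
  8–20% and the saturating rise fit underestimate τ by 15–50% — effects a
  user should expect on real data, where the fitted constants are
  *effective* values of the chosen measurement convention, not deconvolved
  biophysical constants.
* **Quantal recordings**: Poisson event times at `miniRate` events/s,
  amplitude `baselineF · amplitude` per event, multiplicative exponential
  bleaching (`bleach` = remaining fraction at the end of the recording;
  0.97 emulates the typical 2–5% loss over 60 s of widefield imaging; a
  linear option exercises the linear bleach correction), additive Gaussian
  noise. Not emulated: shot-noise scaling with intensity, motion
  artifacts, focus drift, amplitude variability of minis (events share one
  amplitude so detection statistics have a clean operating point).
* **Evoked recordings**: one deterministic kernel per stimulus scaled by a
  per-stimulus gain, linear superposition; an optional reference channel
  carries its own baseline, bleach and noise but no events.
* **Matched pairs**: bivariate lognormal amplitudes; the `rho` parameter
  targets the *Pearson* correlation of the pairs — the log-scale
  correlation is set to log(1 + ρ(e^(σ²) − 1))/σ², which the lognormal
  attenuation maps back to ρ on the linear scale. Event times sit on a
  jittered grid with a guaranteed minimum separation of half the nominal
  spacing, so a ≤10 ms optical jitter can never make the correspondence
  ambiguous (with uniformly scattered times, chance near-coincidences
  mispair ~1.5% of events and visibly attenuate the recovered r).
* **AZ matrices**: per-AZ means plus i.i.d. Gaussian noise in the standard
  30 AZ × 15 stimulus design.

Because the generator's noise is Gaussian, events are identical in shape,
and baselines are stationary apart from smooth bleaching, a green test
suite demonstrates the *algorithms* are correct and calibrated under these
conditions — not that any particular sensitivity or precision will be
attained on real recordings with correlated noise, variable quantal sizes
and unstable baselines.

## Validation problem sizes

The test suite validates the baseline estimator against a brute-force
sort-and-select oracle on 1000 random traces (lengths 10–500, windows
3–101); kinetics on 800 fitted events per regime (100 seeds × 8 events) at
100 fps and SNR 10 for the (τ~rise~, τ~decay~) regimes (5, 67), (14, 42),
(14, 67) and (21, 99) ms; detection on one hundred 60 s traces at 0.5
events/s; correlation recovery on 500 replicates per ρ ∈ {0.46, 0.73,
0.81} at n ∈ {283, 298, 216}; and AZ-test size on 1000 null replicates of
the 30 × 15 design, using the exact binomial reference interval for the
rejection count of a fixed AZ pair. Median decay errors are under 2%
in all regimes; median rise errors are within 25% except in the
(14, 42) regime, where most rises span fewer than three frame intervals at
100 fps and are reported as unresolved — the corresponding acceptance
check is expected to fail, by design rather than by accident, and the
event-level diagnostics (`converged`, `note`) make the limitation visible
in real analyses too.

## Known limitations

* Rise constants at or below ~1.5 frame intervals are not estimable; they
  are bounded, flagged, and reported as the midpoint of the feasible
  interval.
* Overlapping events closer than roughly one rise time merge into a single
  detected peak; the detector does not deconvolve.
* The decay fit reports the effective single-exponential constant of the
  chosen span; multi-exponential decays and indicator biophysics are out
  of scope.
* XLSX input is supported (via readxl); table output is CSV.
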