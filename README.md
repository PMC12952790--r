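# quantaflux

Headless analysis of quantal and evoked Ca²⁺ transients from fluorescence
time series.

Synaptic calcium imaging with genetically encoded indicators (GCaMP and
relatives) produces ROI mean-intensity traces in which spontaneous quantal
events ("minis") and stimulus-evoked transients must be normalized,
detected, and kinetically characterized. quantaflux implements that
pipeline for anyone analyzing such traces — imaging tables exported from
Fiji/ImageJ in, event tables and summary statistics out — with no GUI and
full scriptability, plus the statistics layer needed when optical events
are recorded simultaneously with electrophysiology.

## The core computations

* **Normalization.** A time-varying baseline F₀(t) is estimated by a
  sliding-window percentile (default: 101-frame window, 30th percentile;
  linear-interpolation convention), and

  ΔF/F(t) = [F(t) − F₀(t)] / F₀(t).

  For dual-channel (indicator + calcium-insensitive reference) recordings,
  R(t) = F_sig(t)/F_ref(t) is normalized the same way — baseline R₀(t)
  from the mean of the lowest 10% of ratio values per window by default —
  giving ΔR/R(t), which cancels expression-level and illumination gain.
  Benchmark-style helpers provide linear bleach correction from
  pre-stimulus windows and constant rest-window normalization
  (F_stim − F_rest)/F_rest.

* **Detection.** Local maxima filtered by threshold amplitude, width at
  half height, and minimum inter-peak distance (larger peak wins; optional
  pre-detection moving average for near-threshold minis), plus manual
  nearest-peak rescue.

* **Kinetics.** Per event, τ_decay from y(t) = y_peak·e^(−t/τ) (LM least
  squares, log-linear initialization) and τ_rise from
  y(t) = A·(1 − e^(−(t−t₀)/τ)), with sampling-limited rises flagged and
  bounded. Benchmark mode: ΔF/F = A₀·e^(bt), τ = 1000/(−b) ms, and sweep
  alignment placing the first rise half a sampling interval after the
  stimulus.

* **Protocols.** Events are partitioned across stimulation-frequency
  blocks (e.g. 1 Hz vs 21.3 Hz); train summaries report first/final
  amplitudes from the pre-train baseline, the facilitation index
  (final/first), and the post-train decay constant.

* **Paired statistics.** Greedy nearest-in-time one-to-one matching of
  optical events to electrophysiological minis within ±50 ms, detection
  fraction, Pearson amplitude correlation, paired t-tests between every
  pair of active zones, IQR flagging of outlier active zones, and
  two-sample Kolmogorov–Smirnov comparisons.

* **Synthetic data.** Seeded generators for quantal and evoked recordings
  (single- or dual-channel, with bleaching and noise), matched
  optical/ephys event streams with controlled correlation and dropout,
  and active-zone response matrices — each with ground truth, so every
  stage is testable end to end.

## Worked example

Simulate a 60 s mini recording (0.5 events/s, ΔF/F amplitude 0.35,
τ_rise 14 ms, τ_decay 67 ms, 3% photobleaching), normalize, detect and fit:

```r
library(quantaflux)

sim <- simulateQuantalRecording(simSpec(
  durationMs = 60000, frameRate = 100, baselineF = 100,
  amplitude = 0.35, tauRise = 14, tauDecay = 67,
  miniRate = 0.5, noiseSigma = 1, bleach = 0.97, seed = 42))

tr <- normalizeDFF(sim$recording)
tr
#> NormalizedTrace 'sim' (DFF): 6000 frames at 100 fps
#>   values range [-0.03886, 0.5645]; baseline range [96.3, 101.1]

ev <- detectPeaks(tr, detectionSettings(threshold = 0.1,
                                        minDistance = 100, smoothWindow = 5))
ev <- fitEvents(tr, ev)
nrow(ev); nrow(sim$truth)
#> [1] 35
#> [1] 37
head(ev[, c("peak_time", "amplitude", "tau_rise", "tau_decay", "converged")], 5)
#>   peak_time amplitude tau_rise tau_decay converged
#> 1       270     0.266     8.35      63.9      TRUE
#> 2       470     0.291    14.44      64.6      TRUE
#> 3      4980     0.280    17.28      68.1      TRUE
#> 4      7080     0.276    14.02      68.9      TRUE
#> 5      8110     0.278    21.78      60.2      TRUE
median(ev$tau_decay, na.rm = TRUE)
#> [1] 67.6
```

35 of 37 true events are recovered (the misses are overlapping close
pairs), amplitudes sit near the simulated 0.35 minus the smoothing
attenuation, and the median fitted decay constant (67.6 ms) recovers the
ground truth (67 ms) to ~1%. The same stages run file-to-file through the
YAML-configured commands (`cmdNormalize`, `cmdDetectFit`, `cmdEvoked`,
`cmdMatch`, `cmdAzStats`, `cmdSimulate`) or the thin CLI at
`inst/scripts/quantaflux` with subcommands `normalize`, `detect-fit`,
`evoked`, `match`, `az-stats`, `simulate`; every run writes its fully
resolved configuration next to the outputs.

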