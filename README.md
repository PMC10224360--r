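# electrome

Band-power and time-dispersion analysis of plant electrophysiological signals.

Plants maintain spontaneous micro-voltage electrical activity (their
*electrome*), recordable from stem tissue as an electrophytogram (EPG): the
difference of potential between two electrodes (DDP, in μV) sampled at a few
tens of Hz for hours. A productive way to analyse such signals is to borrow
the EEG band-power toolkit: estimate a power spectral density (PSD) per time
slice, integrate it over named frequency bands, and track how the energy in
each band evolves before and after a stimulus — for example, presenting a
potential host plant to a parasitic dodder. This package implements that
pipeline for researchers in plant electrophysiology, together with a
synthetic electrome generator with known ground truth, so every stage can be
validated without access to field recordings.

## The method

For each recording `x(t)` sampled at `fs` Hz (default 62.5 Hz, 2 h phases,
i.e. 450,000 samples), split into consecutive 60 s windows and compute per
window:

- **Mean frequency** — the spectral centroid of the detrended window,
  `Σ fᵢ Pᵢ / Σ Pᵢ`, with `Pᵢ = |X(fᵢ)|²` from the real FFT over positive
  frequencies (an amplitude-weighted variant is available).
- **Mean DDP** — the arithmetic mean of the raw window (μV).
- **Average band power (ABP)** — the Welch PSD of the window (4 s Hann
  segments, 50 % overlap, per-segment constant detrend, one-sided density in
  μV²/Hz), integrated over each band with the composite Simpson rule:

  `ABP(band) = ∫_band Ŝ(f) df  (composite Simpson on the Welch grid)`

  over the seven EPG bands: low 0–0.5 Hz, delta 0.5–4, theta 4–8, mu 9–11,
  alpha 8–13, beta 13–30, gamma 20–100 Hz (bands reaching past the Nyquist
  frequency `fs/2 = 31.25` Hz are clipped, with a warning).

**TDAF** (time dispersion analysis of features) then aggregates each feature
across replicate plants: per minute, the median, quartiles (linear
interpolation between order statistics), minimum and maximum, plotted in
temporal order; phases are compared by the ratio of pooled medians and a
threshold-based onset estimate.

The synthetic generator produces cohorts with a `1/f^β` coloured-noise
background plus band-limited oscillatory components calibrated by rms
amplitude; a step modulation can multiply in-band component power by a known
gain from a fixed onset — emulating the sustained low-band energy rise a
dodder shows ~20 min after presentation of a suitable host.

## Worked example

Simulate a 5-plant cohort with 10-minute phases whose low-band power triples
120 s into the after phase, extract per-minute features, aggregate with TDAF
and compare phases:

```r
library(electrome)

cfg <- generator_config(
  duration_s = 600, n_replicates = 5, base_seed = 42,
  modulation = step_modulation(onset_s = 120, band_gains = c(low = 3))
)
cohort <- generate_cohort(cfg, treatment = "host")
feats  <- epg_features(cohort)          # warns: gamma band clipped at 31.25 Hz
tdaf   <- tdaf_aggregate(feats)
pc     <- compare_phases(tdaf)
dplyr::filter(pc, band == "low")
#>   treatment feature band median_before median_after after_before_ratio onset_minute
#> 1      host abp:low  low      2476.649     6959.808           2.810172            1
```

The low-band ABP median rises from ~2477 μV² to ~6960 μV², a ratio of 2.81
against the programmed power gain of 3 — the shortfall is the unmodulated
in-band share of the 1/f background plus Welch sampling variability at this
small scale. The true onset is minute 2 (120 s); with only 5 replicates the
threshold detector fires one minute early here, while at the study scale
(23 replicates, 2 h phases) it lands on the programmed minute exactly.
`autoplot(tdaf)` draws the minute-by-minute median with min–max and
interquartile shading per feature, before phase in green, after in blue.

A thin command-line interface wraps the same functions:

```sh
inst/cli/electrome run --manifest run.json --out results/ --seed 1
```

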