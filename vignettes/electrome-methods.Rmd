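---
title: "Methods: band power and time dispersion analysis of plant electromes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: band power and time dispersion analysis of plant electromes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(electrome)
```

## The signal and the analysis model

An electrophytogram (EPG) recording is a micro-voltage time series: the
difference of electrical potential between two electrodes inserted in plant
tissue (DDP, μV), sampled uniformly at `fs` Hz. The package's reference
conditions are `fs = 62.5` Hz and 2 h (7200 s) phases — 450,000 samples per
phase — with 23 replicate plants per treatment and a before/after phase
structure around a stimulus such as the presentation of a potential host.

The analysis treats each recording as locally stationary on the scale of one
minute and asks how the signal's energy is distributed over frequency, and
how that distribution evolves. Per 60 s window it computes:

* **mean frequency** (Hz): the spectral centroid of the mean-subtracted
  window, \(\sum_i f_i P_i / \sum_i P_i\) over the positive frequencies of
  the real FFT with \(P_i = |X(f_i)|^2\);
* **mean DDP** (μV): the arithmetic mean of the raw window — deliberately
  *not* detrended, since the local DC level is the quantity of interest;
* **average band power, ABP** (μV²): the Welch power spectral density of the
  mean-subtracted window integrated over each named band with the composite
  Simpson rule.

The seven bands follow EEG nomenclature: low (0–0.5 Hz), delta (0.5–4),
theta (4–8), mu (9–11), alpha (8–13), beta (13–30) and gamma (20–100 Hz).
Bands may overlap (mu ⊂ alpha; beta ∩ gamma ≠ ∅) and are always analysed
independently. At `fs = 62.5` Hz the Nyquist frequency is 31.25 Hz, so the
beta band is fully resolvable but gamma is not: integration is clipped to
[20, 31.25] Hz and a structured warning (`electrome_warning_nyquist_clip`)
is raised and recorded in the pipeline's run log, so published tables are
self-describing about the truncation.

## Welch estimation: parameters and conventions

`welch_psd()` fixes every convention needed to reproduce results bit-for-bit:

| parameter | default | units | rationale |
|---|---|---|---|
| `window_seconds` | 4 | s | 250-sample segments; Δf = 0.25 Hz resolves the 0.5 Hz low/delta edge |
| `overlap_fraction` | 0.5 | — | standard variance/bias compromise for Hann segments |
| `taper` | Hann (periodic) | — | sidelobe suppression; periodic form matches the common scientific-stack default |
| detrend | constant per segment | — | removes the local DC level only |
| scaling | one-sided density | μV²/Hz | the integral over [0, fs/2] approximates the window variance |

A 60 s window therefore yields 29 averaged segments and a 126-point grid
from 0 to 31.25 Hz. The density is taper-power corrected
(division by `fs · Σw²`) with all bins except DC and Nyquist doubled.

**Band integration.** `band_power()` applies the composite Simpson rule to
the in-band grid points, inclusive at both edges. When the in-band interval
count is odd, the first interval is handled by the trapezoid rule and
Simpson covers the remainder (both rules are exact for linear densities, so
the hybrid retains exactness on smooth, slowly varying spectra). With fewer
than three in-band points the integral falls back to the trapezoid rule with
a warning; a single in-band point integrates to zero (a measure-zero cell);
a band lying entirely above Nyquist is an error naming the band. Adjacent
bands that share an edge (0.5, 4, 8 Hz) both include the shared grid point —
harmless for integrals, whose shared edges carry zero measure.

**A numerical property worth knowing: Simpson on line spectra.** Simpson
weights assume a smooth integrand. A pure tone lying exactly on the Welch
grid produces a 3-bin Hann main lobe with relative powers (¼, 1, ¼); the
rectangle-rule sum of those bins recovers the full tone power `A²/2`, but
composite Simpson assigns them weights (4, 2, 4)·h/3 and returns exactly 8/9
of it — an 11.1 % underestimate of an isolated on-grid spectral line. The
effect vanishes for broadband signals (where the density varies slowly on
the grid scale) and is documented in the test suite, which pins both the
rectangle-sum identity (50 μV² for a 10 μV tone) and the Simpson value
(400/9 μV²), cross-checked against an independent reference implementation.
Simpson integration is retained because ABP is defined on broadband
densities; users integrating line spectra should interpret absolute levels
accordingly (band *ratios* of a scaled tone are unaffected, since the bias
is multiplicative).

**Parseval contract.** For windows whose power lies above the first Welch
bin (0.25 Hz), the band powers of a contiguous partition of [0, fs/2] sum to
the window variance to within a few percent (worst case ~3 % over 50 white
noise windows in the acceptance suite; the residual is Welch's taper
weighting and per-segment detrending). The contract deliberately excludes
signals dominated by frequencies below the segment resolution: a 1/f
background shaped over a 2 h recording carries a large share of its variance
below 0.25 Hz, where per-segment constant detrending removes it from the
density but not from the variance. This is a property of any short-segment
Welch estimator, not of the implementation.

## The synthetic electrome generator

No raw plant recordings ship with the package; the generator replaces them
with signals whose ground truth is known exactly:

* **Background**: white Gaussian noise spectrally shaped to `1/f^β` by
  scaling its rFFT coefficients by `f^(−β/2)` and zeroing DC, then rescaled
  to a target rms. Defaults `β = 1`, rms 20 μV. Shaping the transform gives
  an exactly controllable spectrum; the recovered log–log PSD slope matches
  −β within ±0.15 across β ∈ {0.5, 1, 1.5} in the acceptance suite.
* **Components**: band-limited Gaussian noise (brick-wall rFFT mask over
  `center ± bandwidth/2`, rescaled to target rms); `bandwidth = 0`
  degenerates to a pure sinusoid with uniformly random phase and amplitude
  `rms·√2`. Amplitudes are calibrated by rms, not peak, because field
  reports quote amplitude ranges rather than waveforms. The defaults — a
  dominant 0–0.5 Hz component at 60 μV rms and a 0.5–3.5 Hz component at
  15 μV rms — place most energy in the low band, consistent with electromes
  whose activity concentrates below 0.5 Hz, and keep the total signal
  (≈ 66 μV rms) with excursions inside the 5–250 μV range reported for
  plant surface potentials.
* **Step modulation**: from `onset_s` (default 1200 s = minute 20) of the
  *after* phase, components whose centre lies in a named band have their
  amplitude multiplied by `√gain` (power by `gain`; default low-band gain 3).
  This emulates a sustained low-band energy rise following host presentation.
  Only components are modulated; the background is treated as
  stimulus-independent instrument/tissue noise.
* **Seeds**: each recording's seed is
  `base_seed + 10007·replicate_index + (phase == "after")`, making cohorts
  bit-reproducible while keeping replicates and phases on independent
  streams. The generator restores the caller's RNG state.

What the generator does *not* emulate: electrode drift, clipped samples,
action or variation potentials, Ca²⁺-wave dynamics, the acquisition
hardware's 0.05–100 Hz analogue band or its 60 Hz notch (generated content
is already band-limited below Nyquist). Passing tests on synthetic cohorts
therefore validate the *pipeline's* correctness and parameter recovery, not
any biological claim about real recordings.

## TDAF and phase comparison

`tdaf_aggregate()` summarises each minute across replicates with the median,
quartiles, minimum and maximum. The quartile convention is fixed to linear
interpolation between order statistics (`stats::quantile` type 7) so that
independent implementations agree exactly; the suite verifies exact
agreement with a sort-based oracle for every cohort size from 1 to 23. Both
the min–max range and the interquartile range are emitted (and drawn by
`autoplot()`, min–max as the outer shading).

`compare_phases()` reports, per feature: pooled phase medians (median of the
per-minute medians), their after/before ratio (left `NA` when the before
median is not positive), and an onset estimate — the first after-phase
minute from which the per-minute median strictly exceeds the before phase's
pooled upper quartile (median of the per-minute q3) for at least
`onset_min_run` consecutive minutes (default 5). The threshold and run
length make the detector deliberately simple and transparent; it is a
screening aid with minute-level uncertainty at small cohort sizes, not a
changepoint model, and it carries no fidelity claim beyond its stated rule.

## Degenerate inputs and tie-breaks

* An all-constant window has no defined spectral centroid; `mean_frequency()`
  raises `electrome_error_undefined_centroid` rather than returning 0.
* A recording shorter than one analysis window, or a Welch input shorter
  than one segment, is a `too_short` error.
* A band-limited component narrower than one FFT bin keeps the single bin
  nearest its centre, so a valid configuration never silently produces
  silence.
* Equal-power tones contribute symmetrically to the centroid; ties in order
  statistics resolve by the interpolation formula itself.
* File I/O distinguishes its failure modes by condition class (missing
  sidecar, non-finite values, non-monotone time, sampling-rate mismatch
  above 1 %), and voltages are serialized with 17 significant digits so
  write→read round-trips are bit-identical.

## Problem sizes used by the test suite

Unit tests run on 1–30 minute synthetic recordings with 1–3 replicates —
sizes chosen so the full suite completes in well under two minutes while
every contract is still exercised. The acceptance-style tests use the
reference study conditions themselves: 450,000-sample phases, 23 replicates
per treatment, 50 Parseval windows, 100 DFT-oracle windows of up to 1024
samples, and 1000 TDAF minutes per cohort size. `scripts/acceptance.R`
re-derives all of these from a single `--seed` in about 90 s on one CPU.

## Known limitations

* Absolute ABP of narrowband (line-like) spectral features is biased low by
  up to 1/9 under Simpson integration, as analysed above.
* Energy below the 0.25 Hz Welch resolution is invisible to the default
  4 s segments; slow drifts are removed per segment, not measured.
* The onset detector's minute resolution and threshold sensitivity make it
  reliable only when the effect size is large relative to the before-phase
  interquartile spread.
* No artifact rejection (drift, clipping, electrode pops) is implemented;
  inputs are assumed clean and gain-corrected to μV.
* No inferential statistics across treatments are provided; the phase
  comparison is descriptive.
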