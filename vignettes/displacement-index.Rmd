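---
title: "Quantifying transport vibration with the Displacement Index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transport vibration with the Displacement Index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roadvib)
```

## The problem

Liquid-preserved boar semen is delivered from AI centers to sow farms in
ordinary road vehicles. Unlike temperature, the vibration exposure of the
doses is rarely monitored, although road shocks are suspected to degrade
sperm quality. `roadvib` provides the analysis side of such a monitoring
system: it converts tri-axial accelerometer recordings made next to the
transported doses into a per-second vibration-intensity statistic, and
builds trial-level and delivery-level analyses on top of it.

## The statistic

Two consecutive accelerometer readings \(p_m\) and \(p_n\) are treated as
points in acceleration space, and their Euclidean distance
\(D = \lVert p_n - p_m \rVert\) measures how violently the signal moved
between two samples. The **Displacement Index** of second \(k\) is the
mean of the \(f\) distances falling in that second (\(f\) = sampling
frequency), and the trial mean \(\bar{D_x}\) averages the per-second
values over a recording.

Three structural properties drive the design and are enforced as tests:

* **Non-negativity** — \(D_i \ge 0\), with equality exactly when the
  window's signal is constant.
* **Scale equivariance** — the index is linear in the acceleration units,
  so the choice of logger unit (g or m/s²) only scales results. The
  logger format therefore passes units through untouched.
* **Translation invariance** — a constant offset (gravity, sensor bias)
  cancels in every difference, so no gravity compensation is performed
  anywhere.

### Windowing

The statistic's definition divides by \(f\), which implicitly assumes
exactly \(f\) distances per window. We therefore use non-overlapping
windows of exactly \(f\) consecutive distances, aligned to the first
distance (samples 0 and 1), and drop a trailing window with fewer than
\(f\) distances: averaging a partial window over \(f\) would bias it low,
and rescaling it would give it a different variance than its neighbours.
A 60 s recording at 50 Hz consequently yields 2999 distances and 59 full
windows. Alignment to sample blocks rather than wall-clock seconds is a
choice; for a logger with a stable clock the two coincide.

### Quality classes and bins

Two complementary summaries of a trip are provided and deliberately not
merged:

* **Quality classes** for road assessment: good (\(D_i \le 1\)), moderate
  (\(1 < D_i < 1.5\)), bad (\(D_i \ge 1.5\)). The class bounds overlap at
  1.5 when read informally; we resolve the boundary to *bad* so that "at
  least 1.5" holds literally, and the three classes partition
  \([0, \infty)\).
* **Intensity bins** for exposure reporting: default edges
  \(0, 1, 2, 3, 4, 5, \infty\), with the first bin closed at 1 and all
  later bins left-open (`<=1`, `>1-2`, ...). Each second lands in exactly
  one bin; absolute time per bin is the second count. Frequencies are
  computed on seconds, not minutes — recomputing the small bins of a
  long trip from rounded minute totals is unstable, so per-second
  counting is the contract.

## The synthetic-trace generator

No public corpus of transport accelerometer logs exists for this setting,
so the generator is a first-class module: it emulates the statistical
structure the analysis stages consume, with fixed defaults that are not
retuned per experiment.

**Noise model.** Within one homogeneous road stretch, samples are iid
Gaussian per axis around a constant gravity vector. Consecutive-sample
differences are then Gaussian with SD \(\sigma_a\sqrt{2}\) per axis, the
distance \(D\) is \(\sigma_a\sqrt{2}\) times a 3-d chi variate, and

\[ E[D] = \frac{4}{\sqrt{\pi}}\,\sigma_a
   \quad\Longleftrightarrow\quad
   \sigma_a = \frac{\sqrt{\pi}}{4}\,\mathrm{target}. \]

`calibrate_sigma()` is exactly this inversion — linear, exact in
expectation, and verified by a Monte-Carlo test. An iid model (rather
than, say, a random walk) keeps the signal stationary and bounded and
makes this calibration closed-form. Differences of iid samples are MA(1)
correlated; that affects the variance of \(D_i\), not its mean, and the
calibration deliberately targets the mean only.

**Per-trial variation.** A trial's intensity is drawn once as
Normal(`target_dbar`, `between_trial_sd`) truncated at zero (`pmax(0, .)`),
mirroring the between-repetition spread of real test drives. The default
design's 12 category parameters are the published per-category mean and
SD of the trial index; they are data of the study protocol, not tuning
knobs.

**Impulses.** Short shock events (potholes, impacts) arrive as a Poisson
process and add zero-mean Gaussian bursts of at most 0.2 s with amplitude
`impulse_scale` (default 5) times the base noise scale. Defaults per
surface: none on smooth asphalt and cobblestone (whose character is
continuous vibration), 2/min on rough asphalt, 6/min on dirt road (whose
character is irregular individual impacts).

**Seeding.** All generators consume the R RNG under `withr::with_seed`;
multi-trial and multi-segment runs split one base seed by counter
(`seed + i - 1`), so any single trial or segment is reproducible in
isolation and identical seeds give bit-identical traces and log files.

**What the generator does not emulate.** Real road spectra are neither
white nor Gaussian: within-trial \(D_i\) spread is wider in reality (the
generator's per-second values concentrate near the trial mean, so
simulated category min/max ranges are narrower than measured ones), and
vehicle suspension, driver behaviour and speed fluctuation are not
modelled. Tests passing on synthetic data therefore validate the
pipeline's arithmetic, invariances and statistical machinery — not any
claim about a specific real road.

## Trial statistics

The standardized protocol records 60 s at 50 Hz per trial, ten replicates
in each of 12 road-surface × speed categories; the design is
**incomplete** (cobblestone was only driven at 30 and 60 km/h, dirt road
only at 30, rough asphalt up to 120). Three consequences:

* The ANOVA fits observed cells only — missing cells are never imputed.
  With both factors as factors, R aliases the inestimable interaction
  contrasts, so the interaction carries
  \((\text{cells}-1) - df_{\text{speed}} - df_{\text{surface}} = 4\) df
  and the residual \(120 - 12 = 108\) df; these degrees of freedom are
  design-determined and tested as such.
* Sums of squares are sequential (Type I) in the order speed → surface →
  interaction, matching the conventional summary of such trials. With an
  unbalanced or incomplete design the order matters, so it is part of the
  contract.
* Tukey HSD treats all 66 pairs of the 12 cell means as one family, using
  the pooled residual mean square and the Tukey–Kramer standard error;
  `single_factor_view()` then restricts the display to the 17 pairs
  varying only in speed and the 11 varying only in surface. Differences
  are always group I minus group II with cells ordered by surface then
  speed, and confidence limits are reported ordered
  (`ci_lower <= mean_diff <= ci_upper`).

A factor observed at a single level contributes a 0-df row rather than an
error, so partial designs (e.g. all trials at one speed) still analyze.
Degenerate inputs are reported, not hidden: constant data yields zero
effect SS with `NA` F ratios (a numerical guard treats SS below
\(10^{-12}(1 + \sum \bar{D_x}^2)\) as zero), and zero residual variance
makes Tukey p-values 0/1 with a warning.

## Delivery analysis

`detect_segments()` finds maximal runs of consecutive seconds with
\(D_i\) strictly above a threshold (default 3, the access-road
criterion), keeps runs of at least `min_duration` seconds, and can merge
runs separated by at most `gap_tolerance` below-threshold seconds
(default 0, i.e. strictly contiguous). The gap tolerance exists because a
road stretch whose true level sits just above the threshold will
occasionally dip below it for a second; tolerating short dips recovers
the stretch as one segment instead of fragments. Segments are geolocated
by the nearest-in-time GNSS fix at their start and end.

## Numerical and format choices

* Log files are UTF-8 text, one `key=value;...` record per line with the
  record type first; accelerations are serialized at 6 significant
  digits (the logger's own precision class), and round-trip equality is
  defined at that precision. Re-writing the same trace is byte-identical.
* Timestamps are seconds from trace start; absolute date/time lives only
  in the header, since the index needs only relative time.
* Bin edges must be strictly increasing; values outside the binning range
  are an error rather than silently clipped.
* CV is SD/mean × 100 with the sample (n−1) SD throughout; a
  single-trial category reports SD 0 with a warning flag.

## Problem sizes

The test suite and the reproduction script run the full protocol where it
is cheap and scaled versions where full scale adds nothing: the
standardized design is simulated at full size (120 trials × 60 s × 50 Hz)
for the ANOVA checks, calibration recovery uses 100–200 trials per
target, property tests use short traces (8–12 s) at small \(f\) where the
brute-force oracles are exact, and the demonstration delivery is a 4.5
min three-segment route. The whole suite completes in well under a
minute.

## Limitations

* The per-second \(D_i\) distribution within a real trial is unknown
  (only summary statistics are available); the Gaussian stand-in is a
  modelling choice, not an inference, and simulated extreme values are
  conservative.
* The index is a time-domain statistic; no spectral weighting (e.g. ISO
  2631 comfort weighting) is applied, and none is claimed.
* Quality-class proportions of a real delivery depend on the actual route
  composition; the package computes them from data and makes no attempt
  to reproduce any particular trip without its recording.
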