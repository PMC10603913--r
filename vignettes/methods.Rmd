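---
title: "Methods: models, defaults and design choices in puwarn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, defaults and design choices in puwarn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(puwarn)
```

# The problem

Pressure ulcers develop when sustained load on a predilection site impairs
tissue perfusion; the working hypothesis behind this package is that the
impairment is visible as a decline in locally measured tissue SpO2 before
any skin damage appears. `puwarn` implements the computational chain for a
wearable monitoring system that records, at the predilection site, SpO2,
heart rate and skin temperature every minute (with per-reading validity
flags) and a 5×5 pressure-foil frame every five minutes, and it provides a
synthetic generator so the whole chain is testable without clinical data.

This vignette documents the models, the tunable parameters and the places
where the package had to make a design choice the source methodology leaves
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

# The early-warning predictor

For a preprocessed series the predictor computes, per minute,

$$\mathrm{diffSpO2}(t) = \overline{SpO2}_{60\min}(t) -
  \overline{SpO2}_{\mathrm{patient}}(t),$$

the trailing one-hour rolling mean minus the expanding mean of all data
available for the subject up to $t$, and flags
$\mathrm{state}(t) = \texttt{warn}$ iff $\mathrm{diffSpO2}(t) \le
\texttt{thres}$ (inclusive). Parameters, all in `predictor_config()`:

| parameter        | default | units  | rationale |
|------------------|---------|--------|-----------|
| `window`         | 60      | min    | the stated rolling-mean horizon |
| `min_valid_frac` | 0.9     | —      | "at least 90 %" read inclusively (≥); the 54/60 boundary is tested |
| `thres`          | −3      | % pts  | the stated warning threshold |
| `warmup`         | 120     | min    | the expanding mean is meaningless in the first minutes; the horizon is a package choice |
| `merge_gap`      | 60      | min    | warn runs separated by ≤ gap merge into one alarm; the alarm-counting rule is not specified upstream, so it is exposed as configuration |

Choices worth calling out:

* **Right-aligned, inclusive window.** A warning must only use past data,
  so the window ends at (and includes) $t$.
* **Filled values count as valid** both for the 90 % gate and the quality
  factor: forward filling exists precisely to bridge short dropouts, and
  the rolling mean would otherwise rarely be defined on realistic data.
* **Inclusive threshold**: $\mathrm{diffSpO2} = -3$ exactly is a warning.
* Undefined states (gate failed, window underrun, or before `warmup`)
  are a third state, not "normal".

Two exact invariants are enforced by tests: `diff + expanding = rolling`
wherever defined (to 1e−9), and adding a constant to the whole trace
changes nothing (shift invariance).

# Preprocessing

The stage order is fixed: timeline completion → out-of-range deletion →
capped forward fill → quality factor → segmentation. Each step is
idempotent where meaningful and each matches a naive-loop oracle in the
test suite.

* **Range bounds** are not specified upstream; the defaults
  (SpO2 [70, 100] %, HR [30, 220] bpm, temp [25, 45] °C) are adult
  physiological-plausibility bounds and are configurable.
* **Forward fill** caps at 5 min. Leading blanks are never filled; filled
  records carry a `*_filled` marker.
* **Quality factor** is the fraction of valid vital channels at a
  timestamp, i.e. one of {0, ⅓, ⅔, 1}. The pressure channel is *not*
  included: its native 5-min grid differs, and the upstream definition is
  ambiguous on this point. Vitals-only is the package's reading.
* **Segmentation** keeps maximal runs with quality strictly greater than
  the threshold (default ⅔, i.e. at least two of three channels), and
  discards runs shorter than `min_section_length` (default 60 min, so a
  one-hour rolling window fits inside any section). Strict `>` follows the
  stated rule; the default threshold value is a package choice.
* Medians over even counts use the midpoint convention.

# Pressure events, clustering, spike-triggered averaging

**Smoothing.** A zero-phase (forward–backward) low-pass Butterworth filter.
No DSP package is available in the supported stack, so the classical design
(prototype poles, prewarp, bilinear transform) and the
odd-padding/steady-state-initial-conditions filtering are implemented in
the package and pinned by tests to coefficients and outputs frozen from an
independent reference implementation. Defaults: order 2, cutoff 1/30
cycles·min⁻¹ — this preserves ≥ 20-min events while removing minute-scale
jitter. Filter parameters are unspecified upstream and config-exposed.

**Peak detection.** A peak is a sample whose two direct neighbours are
smaller; a plateau of equal values returns its middle sample, the lower
middle on even plateaus (deterministic tie-break). Candidates are filtered
by minimum distance (default 10 min; on conflict the higher-prominence peak
survives — the conflict rule is a package choice), minimum prominence
(default 1 z-unit) and width-at-half-prominence bounds (default 5–120 min).
The surviving width is the event's duration proxy. Falling events are peaks
of the negated series. The detector is verified against brute-force
enumeration over all short series on a three-letter alphabet.

**Windows and clustering.** Events get −5…+55 min windows (61 samples) on
the common 1-min grid; the 5-min pressure series is upsampled by holding
each frame (a forward fill bounded by its native interval); windows
crossing a series boundary or containing a temperature gap are excluded.
Clustering runs k-means with Euclidean distance on the flattened,
per-window rescaled (zero mean, unit variance) load trajectories — the
"time-series k-means with input scaling" of the source toolchain reduces to
exactly this. 10 restarts per candidate K under a fixed seed; K is chosen
by the elbow method, operationalised as the maximum second difference of
inertia over the candidates (default 2–6) — the criterion itself is named
but not specified upstream. Duration classes for reporting (20, 40,
> 55 min) are assigned by nearest bin.

**STA.** For each window the relative temperature is the trajectory minus
its value at the reference sample one minute before the event
(`rel_time = −1`); the STA is the pointwise mean, exactly zero at the
reference index. Pearson and Spearman correlations against the cluster's
pressure centre are reported, absent when either trajectory is constant.
One subtlety the tests encode: the trigger is the load *peak*, which for a
plateau-shaped event is the plateau middle, so under positive lagged
coupling the robust signature is that the STA is higher just after the
trigger than at the window start (temperature still climbing toward its
asymptote on both sides of the reference), not that it rises monotonically
from $t=0$.

# Cohort statistics

Group comparisons run on *per-subject means* (not pooled minutes), which
avoids pseudo-replication; Welch's unequal-variances $t$ with
Welch–Satterthwaite degrees of freedom, two-sided (sidedness is not stated
upstream; two-sided is the conservative reading), flagged at α = 0.001.
The statistic is computed from the textbook formula and cross-checked
against `stats::t.test` in the suite; a null-simulation test checks
calibration of the rejection rate.

# The synthetic generator: what it emulates, what it does not

The generator's defaults are the stated world of the monitored cohorts:

* **Marginal vitals**: patients SpO2 91.3 ± 2.9 %, HR 70.2 ± 10.8 bpm,
  temp 36.0 ± 0.7 °C; controls 98.5 ± 0.9 %, 57.4 ± 7.0 bpm,
  35.3 ± 0.4 °C. The configured sd is the *within-subject marginal* sd of
  an AR(1) (mean-reverting) process with time constant 30 min, so a long
  recording's sample mean converges to the configured mean — this is what
  makes parameter-recovery tests well-posed. A separate `between_sd`
  (default 0) adds subject-level heterogeneity if wanted.
* **Condition contrasts**: a prior PU surgery shifts a patient's SpO2 by
  −2.2 points and skin temperature by −0.7 °C, applied mean-preservingly
  (`(flag − prevalence) × offset`, prevalence 0.30), which reproduces both
  the subgroup means (≈ 89.8 vs 92 % SpO2, 35.5 vs 36.2 °C) and the
  overall patient means without double-counting.
* **Pressure events**: boxcar loads on a central 3×3 sub-block of the 5×5
  grid (the spatial load shape is unspecified upstream; a fixed block is
  the simplest faithful choice), scheduled either explicitly or with
  durations cycled from {20, 40, 60} min and exponential gaps.
* **Temperature coupling**: skin temperature follows the z-scored total
  load through a linear gain (0.5 °C per z-unit) with a first-order 5-min
  lag — rising load warms the site with minimal delay, pressure relief
  cools it. The exact physiology is unspecified; this is the minimal model
  with the right sign and timescale.
* **Corruption**: each channel is independently invalid as a two-state
  Markov process (default long-run invalid fraction 25 % for SpO2/HR, 2 %
  for the more reliable temperature sensor; mean burst 5 min), producing
  the burst-like validity structure of real recordings; whole-record gap
  minutes emulate missing timestamps. Raw light-sensor signals are *not*
  modelled — validity is generated as flags directly.
* **PU episodes**: `inject_pu_episode()` superimposes a linear SpO2
  decline (e.g. 7 points over 90 min) with a hold, preserving noise and
  validity structure.

A green test on synthetic data establishes that the *computational chain*
behaves as specified under the stated statistical structure. It does not
establish clinical validity: the generator has no motion artifacts
correlated across channels, no posture dynamics, no circadian structure,
and its event shapes are idealised boxcars.

# Numerical choices and degenerate inputs

* z-scoring uses the population convention; constant input yields zeros
  with a warning.
* Constant-group Welch tests degenerate to $t = 0, p = 1$ (equal means) or
  $p = 0$ (different constant means).
* Sections shorter than the filter warm-up are passed through unsmoothed
  with a warning rather than dropped silently.
* `stats::kmeans` requires $K$ strictly below the number of windows and at
  most the number of *distinct* scaled trajectories (noise-free duplicates
  collapse); unusable candidate $K$s are skipped with a warning.
* CSV round-trips write 17 significant digits; blanks are empty cells,
  flags 0/1, timestamps ISO 8601 UTC with an internal integer-minute
  clock.
* All randomness flows through explicit seeds; per-subject seeds are
  derived from a master seed, and repeated runs are bit-identical (the
  pipeline manifest records md5 sums).

# Insole analysis

The 12 rows of the 4×12 insole grid map to forefoot (rows 1–5, toe row
first), midfoot (6–8) and rearfoot (9–12); the mapping is unspecified
upstream, approximates anatomical proportions, and is overridable. Loads
are divided by subject weight; "peak" is operationalised as each subject's
maximum frame value, averaged across the group, and group means aggregate
over all frames of all subjects (frame-weighted) — both aggregation orders
were open choices and are documented here. Region sums partition the frame
total exactly, by construction and by test.

# Known limitations

* The predictor's parameters are heuristics inherited from the method
  description; ROC-based optimisation is explicitly out of scope.
* Alarm counting depends on `merge_gap`; with the default 60 min the alarm
  counts of any real recording are not comparable to counts produced under
  other merging conventions.
* The elbow criterion (max second difference) can be unstable when the
  inertia curve is nearly linear; fix K explicitly (as the
  duration-recovery experiment does) when the cluster count is known.
* Generator realism limits listed above; in particular noisy patient-level
  traces produce occasional false alarms, which is consistent with the
  behaviour of the predictor on real data but means alarm counts on
  synthetic cohorts are generator-parameter-dependent.
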