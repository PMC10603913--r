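# puwarn — pressure-ulcer early warning from wearable sensor streams

`puwarn` is an R package for analysing data from a wearable pressure-ulcer
(PU) monitoring system: a sensor node recording tissue SpO2 (%), heart rate
(bpm) and skin temperature (°C) every minute at a predilection site (sacrum
or trochanter), next to a pressure-sensitive foil (5×5 elements, one frame
every 5 min; a 12×4 insole variant for the diabetic-foot setting). It is
aimed at researchers prototyping PU prophylaxis analytics who need the full
chain — preprocessing, pressure-event analysis, early-warning prediction,
cohort statistics — runnable and testable without access to clinical data.

## What it computes

**Early-warning predictor.** The core statistic is the difference between
the trailing one-hour rolling mean of tissue SpO2 and the expanding mean of
all data observed so far for that subject:

    diffSpO2(t) = mean_60min(SpO2)(t) − mean_patient(SpO2)(t)
    state(t)    = warn    if diffSpO2(t) ≤ thres      (default thres = −3)
                  normal  otherwise

The rolling mean is only evaluated when at least 90 % of the SpO2 samples in
the window are valid. Consecutive warn minutes are merged into alarm events.
A decline of ≈7 percentage points over 1.5 h — the pattern preceding a
diagnosed stage-one PU — triggers a warning during the decline, roughly two
hours before the Phillips finger test turns positive.

**Preprocessing.** Timeline completion (missing timestamps become blanks),
deletion of out-of-range values, forward filling capped at 5 min, a
per-timestamp data-quality factor (fraction of valid channels), and
segmentation into relevant sections where quality exceeds a threshold.

**Pressure–temperature response.** Butterworth smoothing and z-scoring of
the total load; peak detection with prominence/width/distance filters
(width at half prominence = event duration); −5…+55 min event windows;
time-series k-means over per-window rescaled load trajectories with elbow
selection of K; and spike-triggered averaging (STA) of the temperature
response relative to the sample one minute before the event, with Pearson
and Spearman agreement between the pressure cluster centre and the STA.

**Cohort statistics.** Per-subject means over valid samples and Welch's
unequal-variances t-tests (α = 0.001) between patients and controls and
across preexisting-condition strata.

**Foot pressure.** Weight-normalised insole loads summarised per
forefoot/midfoot/rearfoot region (mean and per-subject peak), compared
across orthopedic-shoe, regular-shoe and control groups.

**Synthetic cohorts.** Because the underlying clinical dataset is not
redistributable, a generator emulates the sensor system: AR(1) vitals
around group means (patients 91.3 ± 2.9 % SpO2, 70.2 ± 10.8 bpm,
36.0 ± 0.7 °C; controls 98.5 ± 0.9 %, 57.4 ± 7.0 bpm, 35.3 ± 0.4 °C),
pressure-load events coupled into skin temperature through a lagged gain,
burst-structured validity flags, and injectable pre-diagnosis SpO2
declines. All analyses are exercised end-to-end on these streams.

## Worked example

```r
library(puwarn)
ds <- generate_cohort(3, 2, generator_config(duration = 1440), seed = 1)
sm <- subject_means(ds)
sm[, c("subject_id","group","spo2_mean","hr_mean","temp_mean")]
#>   subject_id   group spo2_mean hr_mean temp_mean
#> 1       P001 patient     92.31   73.89     36.44
#> 2       P002 patient     91.61   68.60     35.99
#> 3       P003 patient     92.54   71.69     36.08
#> 4       C001 control     98.76   57.01     35.33
#> 5       C002 control     98.55   57.03     35.35

compare_groups(sm)[, c("channel","mean_a","mean_b","t","p","significant")]
#>              channel mean_a mean_b       t       p significant
#> 1               spo2   92.2   98.7 -21.696 0.00067        TRUE
#> 2                 hr   71.4   57.0   9.367 0.01120       FALSE
#> 3               temp   36.2   35.3   6.071 0.02507       FALSE
#> 4 mean_pressure_load   62.9   62.1   0.516 0.67018       FALSE
```

Patients sit ~6.5 SpO2 points below controls — with only 3 + 2 subjects the
SpO2 gap is already significant at α = 0.001, heart rate and temperature are
not, and mean pressure load is similar in both groups (it does not explain
the vital-sign differences). Now stamp a PU-like decline (7 points over
90 min) onto one subject and run the predictor over the cohort:

```r
target <- names(ds$subjects)[1]
ds$subjects[[target]]$vitals <- inject_pu_episode(
  ds$subjects[[target]]$vitals, onset = 600, drop = 7,
  decline_duration = 90, hold_duration = 60)
al <- evaluate_cohort(ds)
vapply(al, `[[`, 0L, "n_alarms")
#> P001 P002 P003 C001 C002
#>    1    2    2    0    0
al[[target]]$alarm_intervals
#>   start end
#> 1   713 781
```

The injected subject alarms inside the episode (decline ends at t = 690).
The other patients raise occasional alarms from their noisy, low-SpO2
traces — the same false-alarm behaviour the predictor shows on real
study data — while the stable controls stay silent.

A full pipeline run (CSV artifacts plus a seed/md5 manifest):

```r
run_pipeline(run_config(n_patients = 2, n_controls = 1, seed = 1), "out/")
```

or from the shell: `inst/scripts/puwarn run-all --n-patients 2
--n-controls 1 --duration 1440 --seed 1 --out-dir out/`.

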