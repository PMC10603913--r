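Package: puwarn
Title: Pressure-Ulcer Early Warning from Wearable Sensor Streams
Version: 0.1.0
Authors@R:
    person("KIPRODE", "Analysis Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for wearable pressure-ulcer (PU) monitoring
    data: per-minute tissue SpO2, heart rate and skin temperature streams with
    validity flags, plus 5-minute pressure-grid frames recorded at a
    predilection site. Implements timeline normalisation, out-of-range
    removal, capped forward filling, a per-timestamp data-quality factor and
    quality-thresholded section segmentation; pressure-event detection
    (Butterworth smoothing, z-scoring, prominence/width-filtered peak
    detection), duration clustering by time-series k-means with elbow
    selection, and spike-triggered averaging of the skin-temperature
    response; the diffSpO2 early-warning predictor (1-h rolling mean minus
    expanding patient mean with a validity gate and warn threshold); Welch
    unequal-variances cohort comparisons; and weight-normalised insole
    pressure-region summaries (forefoot/midfoot/rearfoot). A synthetic-data
    generator emulates the sensor system so that every stage is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
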