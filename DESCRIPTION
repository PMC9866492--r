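Package: triposture
Title: Detailed Sedentary Posture Analysis from a Tri-Monitor Accelerometer Configuration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates hip and knee flexion angles from three body-worn
    accelerometers (torso, thigh, shin) and partitions free-living sedentary
    time into lying, bent-legged sitting and straight-legged sitting. Reads
    raw triaxial acceleration exports in two device dialects, applies a
    zero-lag first-order Butterworth low-pass to isolate the gravity
    component, computes inter-segment angles by the dot-product method,
    intersects thigh-classified sedentary bouts with diary-reported waking
    windows, accumulates dwell time in 15-degree angle bins split by
    prolonged (>1 h) versus non-prolonged bouts, aggregates to minutes per
    day, and compares postures across participants with Wilcoxon signed-rank
    tests under a Bonferroni-adjusted alpha. A synthetic-scenario generator
    renders three-monitor signals from known posture schedules so every
    pipeline stage can be validated against analytic ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
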