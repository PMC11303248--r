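Package: complexwheel
Title: Complex-Wheel Running Telemetry and Motor-Learning Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Processes running-wheel sensor telemetry from complex (unevenly
    runged) wheels into motor-learning curves: peak detection on analog rung-
    sensor traces, active-period segmentation by a 2-second gap rule,
    revolution reconstruction from rung-intercept counts, sliding-window
    velocity estimation, revolution-window smoothing and distance-binned
    learning curves. Includes a ground-truthed synthetic-data generator for
    sessions, cohorts and OPC (oligodendrocyte progenitor cell) point
    patterns with focal hyperdensities, ROI hyperdensity classification and
    coverage quantification, g-ratio computation, and the statistical
    endpoints used to relate hyperdensity coverage to motor performance
    (milestone group comparisons with Bonferroni correction and ordinary
    least squares regression).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    emmeans,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
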