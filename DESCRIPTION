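Package: hapticube
Title: Haptic Exploration Metrics from Instrumented-Cube Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for haptic exploration recordings from a
    sensorized cube that reports per-face binary touch maps (6 faces x 16
    capacitive cells) and an orientation quaternion at an irregular ~5 Hz
    rate. The pipeline resamples trials to a constant 0.2 s grid (zero-order
    hold for touch, SLERP for orientation), separates explorative from
    holding touches with a simple-matching-coefficient filter, quantifies
    cumulative rotation and rotation speed from per-axis traversal angles,
    builds exploration-sequence transition matrices over relative
    orientation labels, extracts thirteen per-trial metrics, and runs the
    group-discrimination statistics (MANOVA with Roy's largest root, Fisher
    linear discriminant analysis, Welch post hocs with Benjamini-Hochberg
    correction, a BIC Bayes factor for accuracy, one-tailed correlations).
    A scripted exploration-trace simulator generates sessions with known
    ground truth for testing and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    MASS,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
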