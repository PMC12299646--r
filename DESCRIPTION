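Package: scapkin
Title: Scapular Kinematics and EMG Analysis of a Functional Drinking Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end movement-analysis pipeline for a five-phase
    reach-drink-return task recorded with inertial kinematics (100 Hz),
    hand accelerometry (2000 Hz) and surface EMG of six scapular muscles.
    Provides acceleration-based task onset/offset detection and kinematic
    phase segmentation, zero-phase Butterworth filtering, sliding-window
    RMS envelopes with submaximal isometric (SVIC) normalization, per-phase
    range of motion and EMG activity levels, scapulohumeral rhythm, trunk
    compensation, time-to-peak acceleration and log dimensionless jerk
    movement smoothness, ICC(2,k) test-retest reliability with SEM and
    MDC95, normality-gated paired pre-post inference with effect sizes and
    noncentral-t sample-size estimation, and a fully seeded synthetic-data
    generator with ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
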