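Package: emgkalman
Title: Multi-Kalman-Filter Decoding of Arm Kinematics from Surface EMG Envelopes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Continuous, simultaneous decoding of elbow angle and wrist
    position from four-channel surface electromyography (EMG) envelopes
    using linear-Gaussian state-space models. Identifies the transition,
    observation and noise-covariance matrices from windowed training data
    by least squares, runs the standard Kalman recursion to decode test
    data, and selects, by cross-validation, the best state-pair filter
    for each kinematic parameter (the multi-filter scheme), alongside
    single-filter and per-parameter baselines. Includes a synthetic
    two-link-arm session generator, Pearson correlation and normalized
    root-mean-square error scoring, and subject-dependent and
    subject-independent evaluation protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    signal,
    withr
Config/testthat/edition: 3
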