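Package: csmux
Title: Complex-Spike Multiplexing Analysis for Cerebellar Purkinje Cell Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Event-locked analysis of cerebellar Purkinje cell complex spikes
    recorded during repetitive saccade tasks: saccade detection from eye traces,
    Gaussian-kernel firing-rate estimation, preferred-direction assignment,
    amplitude/duration/velocity tuning with linear fits, bootstrap estimation of
    response peak and modulation-onset (trough) times, disentangling of
    error-related from kinematics-related firing by error-vector pooling and
    per-cell multiple regression, complex-spike duration analysis, and per-cell
    encoding matrices with parameter cross-correlations. Ships a synthetic
    oculomotor-session simulator (minimum-jerk saccades with fatigue, corrective
    saccades, inhomogeneous-Poisson spike trains with known tuning) so every
    estimator can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
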