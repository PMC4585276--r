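Package: mepmod
Title: Modular Analysis and Prediction of Muscle Excitations in Human Locomotion
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extracts motor components (non-negative temporal factors and muscle
    weightings) from multi-muscle surface-EMG linear envelopes recorded during
    treadmill locomotion, using non-negative matrix factorization with random
    restarts and variance-accounted-for (VAF) based dimensionality selection.
    Parameterizes the factors as Gaussian excitation primitives, models the
    speed- and elevation-dependence of the muscle weightings with additive
    polynomial regressions anchored at a baseline condition (3 km/h, 0%
    elevation), and predicts full muscle excitation profiles (MEPs) for novel
    locomotion conditions in subject-generic or subject-specific mode. Includes
    the full EMG processing chain (zero-phase Butterworth filtering,
    rectification, amplitude normalization, marker-based gait segmentation,
    200-point time normalization), shift-compensated waveform comparison
    metrics, a ground-truth synthetic data generator, model serialization, and
    a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
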