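Package: sncmeg
Title: Structured-Noise Champagne for Electromagnetic Brain Source Imaging
Version: 0.1.0
Authors@R:
    person("Biomagnetic", "Imaging Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sparse empirical-Bayes source reconstruction for MEG/EEG
    (the Champagne family of solvers) with joint estimation of a
    low-rank-plus-diagonal "structured" sensor-noise covariance via
    variational Bayesian factor analysis of the model residuals, so that
    no baseline (noise-only) recording is required. Includes minimum-norm
    (sLORETA), beamformer (LCMV) and minimum-current (MCE) reference
    solvers, a simulator of damped-sinusoid dipole sources mixed with
    structured noise at controlled SNR, free-response ROC style
    localization metrics, and a command-line interface with a plain-text
    dataset container.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests:
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
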