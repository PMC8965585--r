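Package: painfuse
Title: Multimodal MRI Feature Fusion for Predicting Individual Pain Sensitivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully synthetic-data-testable pipeline for predicting
    an individual's laser pain threshold from multimodal brain MRI features.
    Implements light temporal preprocessing of resting-state BOLD series
    (initial-volume discard, Friston-24 motion expansion, framewise-displacement
    scrubbing with spike regressors, nuisance regression, band-pass filtering),
    extraction of two fMRI feature types (voxel-wise regional homogeneity via
    Kendall's coefficient of concordance; ROI-pair functional connectivity via
    Fisher-z-transformed Pearson correlation) and two diffusion-tensor feature
    types (voxel-wise fractional anisotropy; ROI-pair structural connectivity
    probabilities from stochastic streamline tractography), leave-one-individual-out
    prediction with fold-wise correlation-based feature selection, decision-level
    fusion of single-feature-type regression models, evaluation statistics
    including a z-test for dependent correlations sharing the true labels, and
    selection-frequency stability analysis of predictive features. A synthetic-data
    module generates parcellations, BOLD volumes, tensor fields, motion traces,
    feature tables and staircase-quantised pain thresholds with controllable
    planted signal, so the whole pipeline runs and is tested without any
    external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    mixOmics,
    randomForest,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
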