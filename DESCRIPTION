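Package: phonoPH
Title: Acoustic Screening for Pulmonary Hypertension from Heart Sounds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Speech-recognition-inspired analysis of phonocardiograms for
    non-invasive pulmonary hypertension (PH) screening. Extracts the second
    heart sound (S2) from 20-second phonocardiogram recordings using the
    simultaneously recorded ECG (R- and T-wave detection, a window covering
    30 percent of the cardiac cycle around the T wave), converts S2 snippets
    into mel-frequency cepstral coefficient (MFCC) feature matrices, fits one
    Gaussian mixture model per diagnostic class by Expectation-Maximization,
    and classifies subjects by frame-averaged negative log-likelihood.
    Includes subject-level k-fold cross-validation with confusion metrics
    and ROC construction, comparison against human-reader confusion
    counts, and a fully annotated synthetic PCG+ECG cohort simulator in
    which the A2-P2 splitting interval and the P2/A2 amplitude ratio are
    driven by a virtual mean pulmonary artery pressure, so the entire
    pipeline is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    signal,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    mclust,
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
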