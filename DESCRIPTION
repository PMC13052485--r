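Package: ramanadapt
Title: Raman Spectral Tissue Classification with Deep Transfer Learning and
    Test-Time Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for binary tissue classification from Raman spectra in
    small-cohort settings. Implements the full preprocessing chain for raw
    spectral accumulations (cosmic-ray removal, accumulation averaging,
    instrument-response correction, BubbleFill autofluorescence baseline
    removal, normalization, resampling to a fixed wavenumber grid), a
    ResNet-style one-dimensional convolutional network trained with binary
    cross-entropy, two-stage pre-training on source domains, efficient
    fine-tuning with a half-frozen feature extractor, unsupervised test-time
    adaptation by prediction-entropy minimization, classical SVM and random
    forest comparators with literature peak features and three-step feature
    selection, and a leave-one-patient-out evaluation harness with repeated
    runs, significance tests and univariate per-peak statistics. A synthetic
    Raman cohort simulator with patient structure, class-dependent peaks,
    autofluorescence baselines and domain shift makes every stage testable
    without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    glmnet,
    e1071,
    ranger,
    yaml,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
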