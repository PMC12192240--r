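Package: lungchaos
Title: Chaos-Based Analysis of Mobile-Phone Lung Auscultation for COPD
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying chronic obstructive pulmonary disease
    (COPD) from two-site mobile-phone auscultation recordings using
    nonlinear time-series dynamics. Provides a synthetic cohort and audio
    generator emulating a two-arm spirometry-confirmed study, WAV input
    and signal conditioning, a parameterized library of two-dimensional
    phase-space portraits, Rosenstein maximal-Lyapunov-exponent and
    Grassberger-Procaccia correlation-dimension estimators, an
    unsupervised entropy-minimizing collapse of portrait features to two
    dimensions, per-site and composite ridge-regularized logistic
    classifiers with case-clustered train/test splits, and
    confusion-matrix, subgroup-accuracy and group-comparison reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
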