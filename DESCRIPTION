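Package: ecgbispec
Title: Bispectrum Images and a Compact Convolutional Network for Atrial
    Fibrillation Detection in ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects atrial fibrillation in short ECG segments by
    higher-order spectral analysis.  Estimates the bispectrum (the
    double Fourier transform of the third-order cumulant sequence) of
    5-second ECG windows with direct FFT-based and indirect lag-based
    non-parametric estimators, converts the low-frequency bispectrum
    amplitude into min-max normalized gray images, and classifies the
    images with a compact serial convolutional neural network trained
    by stochastic gradient descent.  Includes a synthetic ECG generator
    emulating normal sinus rhythm and atrial fibrillation (irregular RR
    intervals, absent P waves, 4-9 Hz fibrillatory waves), readers and
    writers for PhysioNet-style WFDB records and rhythm annotations,
    rhythm-episode accounting and fixed-length segmentation, and the
    standard diagnostic-test measures (sensitivity, specificity,
    predictive values, likelihood ratios, F-scores, ROC/AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    stats,
    withr,
    digest
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
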