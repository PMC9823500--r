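Package: eegauth
Title: EEG-Based User Authentication with Wavelet Features and One- and
    Multi-Class Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an electroencephalogram (EEG) biometric
    authentication pipeline: seeded synthesis of multichannel EEG-like
    cohorts with user-specific band-power signatures, discrete wavelet
    (Daubechies order 2) band decomposition with eight summary statistics
    per band, per-user enrollment/authentication splits with impostor
    sampling, six classifier back-ends behind a uniform train/predict
    contract (SVM, random forest, k-nearest neighbours, one-class SVM,
    isolation forest, local outlier factor), principal-component and
    chi-squared feature reduction, confusion/ROC evaluation including the
    equal error rate, and the experiment suite: baselines, channel and
    brainwave ablation, contamination sweeps, and a hybrid one-class to
    multi-class cascade.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    randomForest,
    class,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
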