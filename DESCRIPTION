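Package: bsvm
Title: Threshold-Adjusted Gaussian-Kernel SVM for Imbalanced Binary Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits soft-margin support vector machines with a Gaussian radial
    basis kernel and corrects the decision threshold for class imbalance using
    the b-SVM tuning factor, the signed imbalance of the unbounded support
    vectors. Includes a fast Min-max gamma selection heuristic based on the
    training-set G-mean, a cross-validated gamma selection baseline, a
    cross-validated threshold-tuning baseline, SMOTE minority oversampling,
    G-mean evaluation utilities, an equicorrelated Gaussian simulation
    generator for imbalanced benchmark data, and experiment runners for
    simulation suites and repeated stratified cross-validation.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    MASS,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    e1071,
    kernlab,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
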