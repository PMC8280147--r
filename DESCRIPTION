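Package: validstab
Title: Stability of AUC Performance Estimates Across Validation Regimens
Version: 0.1.0
Authors@R:
    person("validstab", "maintainers", email = "maintainers@validstab.invalid",
           role = c("aut", "cre"))
Description: Quantifies how the choice of internal validation regimen
    (stratified split-sample, k-fold cross-validation with pooled
    out-of-fold predictions, repeated cross-validation, out-of-bag
    bootstrap, leave-one-out) destabilizes AUC-based performance
    estimates of clinical risk classifiers. Provides ROC inference
    (Mann-Whitney AUC, DeLong variance and confidence intervals,
    Hanley-McNeil standard errors, the non-directional test between two
    independent ROC curves), four reference classifiers (logistic
    regression, Gaussian naive Bayes, linear discriminant analysis, and
    a native random forest), mutual-information feature ranking, a
    seed-replication stability harness, and a synthetic clinical cohort
    generator with a linear-logit signal calibrated to a target AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
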