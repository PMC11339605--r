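Package: grouprisk
Title: Group-Level Disease-Rate Estimation from Genetic and Non-Genetic Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing disease-risk distributions across groups and for
    predicting group-level case rates from individual-level genetic (polygenic
    risk score) and non-genetic (pooled-cohort-equation style) risk factors.
    Implements Monte Carlo permutation tests with Benjamini-Hochberg false
    discovery rate control, liability-threshold-model case probabilities,
    standard and Mundlak (within-between) logistic regression with
    leave-one-group-out cross-validation, Wilson score intervals obtained as a
    fixed point, DeLong-variance AUC confidence intervals, and a synthetic
    cohort generator with liability-threshold disease, group structure,
    participation bias and quantile-based group assignment that reproduces the
    reversal of individual- versus group-level associations (Simpson's
    paradox) caused by ascertainment bias.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
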