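Package: prevpool
Title: Prevalence Estimation by Pooling a Gold-Standard Survey with
    Electronic Health Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates a population prevalence by jointly using a large,
    selection-biased and misclassification-prone record source (such as an
    electronic health record system) together with a small gold-standard
    probability survey. Implements two estimators: a logit-scale Mosteller
    pooled estimator that discounts the biased source by its squared
    estimated bias, and a subject-level iterative Bayesian multiple
    imputation estimator that models the misclassification between the two
    outcome measurements on a linked subsample and combines imputations via
    Rubin's rules with Barnard-Rubin degrees of freedom. Includes a full
    two-source linked-sample simulator (correlated misclassified binary
    outcomes, unequal-probability sampling, post-stratification) for
    validating both estimators, plus command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    pracma,
    pROC,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
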