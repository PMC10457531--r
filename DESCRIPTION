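Package: mobcate
Title: Heterogeneous Treatment Effect Discovery by Model-Based Recursive
    Partitioning of Pooled Trial Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting heterogeneous effects of an Internet-based
    depression intervention from pooled individual-participant data of two
    randomized trials in chronic back pain. Provides maximum penalized
    likelihood multilevel linear models with a Wishart prior on the
    random-effects covariance, multilevel multiple imputation by chained
    equations with Rubin's-rules pooling, one-stage meta-analytic average
    treatment effects with reliable-change classification, univariate
    treatment-moderator interaction models with cluster-robust (CR2)
    sensitivity analyses, model-based random forests for permutation variable
    importance, multilevel model-based recursive partitioning with
    parameter-instability tests and Bonferroni pre-pruning, LASSO-penalized
    multivariable interaction models with BIC-selected penalty, bootstrap
    optimism correction, and external-trial transport validation. Includes a
    synthetic-data generator with planted subgroup effects so the entire
    pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    glmnet,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
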