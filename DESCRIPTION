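Package: cbwmsm
Title: Calibrated Covariate Balancing Weights for Marginal Structural Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of marginal structural models for longitudinal
    outcomes with time-varying confounding and dependent dropout, using
    jointly calibrated inverse probability of treatment and censoring
    weights. Initial stabilized weights are fitted by maximum likelihood
    for binary, ordinal (continuation-ratio) or continuous
    (heteroscedastic normal) treatment processes and a pooled logistic
    dropout process; covariate-balance moment conditions for both
    processes are then imposed exactly, either by convex exponential
    tilting of the initial weights or by re-solving the weight-model
    estimating equations. Includes weighted least-squares fitting of the
    marginal structural model, patient-resampling bootstrap standard
    errors, balance diagnostics, and a longitudinal data simulator with
    known causal parameters for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
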