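Package: enviroGP
Title: Multi-Environment Genomic Prediction with Environmental and
    Phenomic Covariates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Multi-kernel Bayesian prediction of line performance in
    multi-environment trials, integrating genome-wide markers,
    environment-level weather covariates (enviromics) and multispectral
    phenomic indices. Provides the relationship kernels (genomic,
    environmental, covariate-informed and their Hadamard-product
    genotype-by-environment interactions), two covariate-selection
    procedures (a cascading Pearson-correlation threshold rule and a
    shadow-feature Boruta algorithm), engineered covariate blocks
    including a sign-aligned average covariate, a Gibbs sampler for the
    resulting mixed kernel/ridge model, fifteen predictor
    configurations, leave-one-environment-out cross-validation with
    NRMSE, relative-efficiency and win-count reporting, and a synthetic
    multi-environment-trial generator with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'kernels.R'
    'bayes-model.R'
    'covariates.R'
    'enviroGP-package.R'
    'feature-selection.R'
    'predictor-registry.R'
    'evaluation.R'
    'io.R'
    'synthetic-data.R'
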