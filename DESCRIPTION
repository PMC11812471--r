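Package: amdprs
Title: Polygenic Risk Scoring and Conformal Disease-Status Prediction for
    Age-Related Macular Degeneration
Version: 0.1.0
Authors@R:
    person("amdprs", "maintainers", email = "maintainers@amdprs.dev",
           role = c("aut", "cre"))
Description: Tools for panel-based weighted polygenic risk score (PRS)
    computation from genotypes of curated AMD risk variants, quintile risk
    group assignment, Mondrian cross-conformal prediction of disease status
    from PRS, age and sex, and stratified validity and error-rate
    evaluation. Includes a synthetic cohort generator that emulates the
    case/control structure of large AMD consortium data (overlapping
    shifted PRS distributions, age and sex covariates) so that the whole
    pipeline is testable without access-restricted genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    glmnet,
    withr
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges
Config/testthat/edition: 3
RoxygenNote: 7.3.3
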