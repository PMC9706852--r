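Package: episig
Title: Polyepigenetic Signatures of Tobacco and Alcohol Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and validation of polyepigenetic exposure signatures
    from blood DNA methylation: candidate-CpG pooling with Bonferroni
    retention, methylation-QTL confounder screening, a randomized best-subset
    logistic model search driven by the Bayesian Information Criterion with
    significance pruning, standardized signature scoring, and downstream
    validation (McFadden pseudo-R2, AUC with DeLong intervals, disease
    association with diagnostics and inverse-probability weighting, Cox
    proportional-hazards and cause-specific competing-risk mortality models).
    Includes a seeded synthetic-cohort generator emulating the joint structure
    of methylation, genotype, exposure, disease and survival data so the whole
    pipeline can be exercised and calibrated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
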