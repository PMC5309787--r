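Package: PreclinRx
Title: Preclinical Drug-Response Analysis for Organoid and Xenograft Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies drug sensitivity of patient-derived organoids (PDO)
    and xenografts (PDX) from raw assay measurements and links it to gene
    expression. Provides plate normalisation and four-parameter logistic
    dose-response fitting with relative IC50, Emax and four-level response
    categories; xenograft endpoint T/C scoring, relative tumour volume with
    RECIST-adapted calls and PDO/PDX sibling concordance; drug-response gene
    signature discovery with FDR and fold-change filters across four
    differential-expression setups; a class-weighted linear support vector
    machine mini-classifier built by recursive feature elimination with
    resampled weight ranking and per-class cost tuning; repeated stratified
    cross-validation and external-cohort validation including a
    mutation-status comparator; and a fully seeded synthetic-cohort
    generator so the whole pipeline is testable without access-controlled
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    e1071,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    kernlab,
    withr,
    testthat (>= 3.0.0)
biocViews: Pharmacogenomics, Classification, GeneExpression, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
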