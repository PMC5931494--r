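Package: vitdmr
Title: Mendelian Randomisation of Vitamin D Status and Type 2 Diabetes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to estimate the causal effect of plasma 25-hydroxyvitamin D
    (25[OH]D) concentration on risk of type 2 diabetes using genetic variants
    as instrumental variables. Provides a synthetic-cohort generator that
    emulates the structure of a large Chinese biobank (four 25[OH]D SNPs,
    latitude and season structure, measured-exposure subset), observational
    logistic analysis with floated absolute risks and forward-stepwise
    covariate adjustment, instrument construction with Hardy-Weinberg checks
    and 10-fold cross-validated allele-score weights, summary-level Mendelian
    randomisation estimators (Wald ratio, fixed-effect inverse-variance
    weighting, MR-Egger, weighted median) and an individual-level allele-score
    instrumental-variable estimator, plus cross-study fixed-effect
    meta-analysis with latitude subgroups and forest tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
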