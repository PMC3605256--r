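Package: cnvburden
Title: Rare Copy-Number and Homozygosity Burden Analysis for Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for case-control analysis of rare structural variation in
    disease cohorts, built for studies of spermatogenic failure but general to
    any rare-variant burden design. Provides multi-algorithm copy-number call
    consensus, reciprocal-overlap clustering of calls into copy-number variable
    regions with cohort-wide frequencies, NAHR hotspot classification, exact
    2x2 locus association (Fisher exact p-values, sample and conditional
    maximum-likelihood odds ratios, Woolf and exact conditional confidence
    intervals), genomewide and per-compartment burden statistics (rank-sum
    tests, covariate-adjusted logistic regression, inverse-variance
    meta-analysis across cohorts, max-T permutation locus tests, gene-set
    burden), post-processing of homozygosity-by-descent segments into
    inbreeding coefficients with uniparental-disomy flagging, a two-dimensional
    exome variant prioritisation score, and a synthetic-data generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    metafor,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
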