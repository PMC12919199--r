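Package: funbat
Title: Cell-Type Functional Burden Association Tests for Rare Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds cell-type-specific gene sets from single-cell expression
    matrices (sensitivity/specificity/AUC profiling and z-score, Wilcoxon,
    expression-proportion and expression-enrichment assignment), applies
    quality-control cascades to annotated rare short variants and copy-number
    variants, collapses variants into binary per-gene per-class disruption
    calls, and tests gene-set functional burdens for association with a
    dichotomous trait using family-stratified conditional logistic regression
    (FunBAT), including a two-burden correction for multigenic copy-number
    variants. Post-hoc utilities cover gene prioritization by gene-set
    downsampling, Fisher-exact enrichments, size-matched effect-size
    normalization against random gene-set nulls, permutation tests for
    subgroup liability biases, and cohort-downsampling stability. A synthetic
    data module generates family-structured cohorts and expression matrices
    with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    survival,
    stats,
    utils,
    jsonlite,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
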