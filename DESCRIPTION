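Package: dietqtl
Title: Age- and Diet-Resolved Genetic Analysis of Body Weight in Diversity
    Outbred Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying how genetics, age, and dietary
    intervention jointly shape a longitudinal quantitative trait in
    multiparent mouse populations. Implements l1 trend filtering of
    per-animal body-weight series, the gene-environment mixed model
    (GxEMM) with per-environment polygenic interaction variances and
    heteroscedastic noise alongside the classic single-component EMMA
    model, total and environment-conditional estimates of the proportion
    of phenotypic variance explained by genetics (PVE), genome-wide
    additive and genotype-diet interaction scans with leave-one-
    chromosome-out kinship and sequential permutation p-values,
    founder-allele-pattern fine-mapping with functional-annotation
    overlap, and weighted likelihood-ratio tests for nonlinear
    age trends in allelic effects. A synthetic diversity-outbred data
    generator reproduces the simulation protocol used to validate the
    model, so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    rtracklayer,
    GenomicRanges,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    MASS
Config/testthat/edition: 3
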