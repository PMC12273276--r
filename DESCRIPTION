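Package: methclass
Title: Ordered DNA Methylation Classes in Metastatic Melanoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovery and transfer of ordered DNA methylation classes
    (DEM < LOW < INT < CIMP) from CpG beta-value matrices of tumor
    cohorts, and their downstream clinical and transcriptional
    characterization.  Implements variance-based CpG panel selection,
    subsampled consensus clustering with delta-area model selection,
    nearest-centroid cohort transfer, promoter methylation-expression
    integration (rank-sum and permutation differential tests, quadrant
    assignment, hypergeometric over-representation), gene-signature
    scoring (median z, HI/LO dichotomization, preranked enrichment,
    upstream-regulator activation z, correlation-filtered signature
    derivation), survival and stage-progression endpoints, and a
    ground-truth synthetic cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    mclust,
    fgsea,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
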