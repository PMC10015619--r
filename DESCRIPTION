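Package: hybridase
Title: Allele-Specific Expression Analysis for F1 Hybrid Crosses
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of allele-specific expression (ASE) in F1 hybrids from
    gene-level allelic read counts across tissues and developmental timepoints.
    Provides exact-test ASE calling with site-level filtering, a Bayesian
    beta-binomial mixture model that classifies each gene's multi-tissue ASE
    pattern (no ASE, uniform ASE, heterogeneous, tissue-specific) with posterior
    probabilities, Fisher's exact testing for differential ASE between
    developmental stages, a gene-set sign test with category-shuffling
    permutations for detecting lineage-specific selection on cis-regulation,
    and SNP-density-controlled permutation/resampling tests for enrichment of
    ASE genes in genomic regions of ecotype divergence. Includes a full
    synthetic-data generator with ground truth for power and calibration
    studies, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    optparse,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
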