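Package: mircontext
Title: Genomic Context, Conservation and Co-Expression Analysis of
    microRNAs in Adipose Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to relate the genomic context of microRNA (miRNA) genes
    to their expression and function in bulk expression profiles, modelled
    on a bovine subcutaneous adipose tissue study design (eight steers,
    three time points). Classifies miRNA precursors as intergenic,
    intronic, exonic or mirtron relative to protein-coding gene models,
    detects genomic miRNA clusters by a same-strand inter-miRNA distance
    rule, derives the tissue "core" miRNA set from detection across
    individuals, fits the power-law relation between mean expression and
    coefficient of variation, builds Pearson relevance networks of
    co-expressed miRNAs, analyses seed-region conservation and
    species-specific seeds with TargetScan-style tables, processes qPCR
    Ct data (replicate aggregation, delta-Ct, delta-delta-Ct fold change,
    host-gene/intronic-miRNA correlation), and performs right-tailed
    Fisher gene-set enrichment. A seeded synthetic-data generator emits
    annotation, expression and qPCR fixtures with known ground truth so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rtracklayer,
    Biostrings,
    igraph,
    fgsea,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
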