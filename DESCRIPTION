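Package: methblocks
Title: Discovery of Large Hypomethylated Blocks and Small DMRs in Array
    and Bisulfite-Sequencing Methylomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects large (hundreds of kilobases to megabases) regions of
    coordinated DNA methylation loss ("blocks") and small differentially
    methylated regions (DMRs) between sample groups, from 450k-style
    methylation array beta values and from whole-genome bisulfite
    sequencing CpG count tables.  Implements open-sea probe collapsing,
    large-window bump hunting with permutation family-wise error control,
    BSmooth-style local-likelihood smoothing with reference-group
    t-statistic segmentation, interval-overlap enrichment against
    reference chromatin domains using width- and probe-matched random
    region nulls, and downstream summaries (block methylation matrices,
    clinical-grade regression, multidimensional scaling, group-trend
    checks).  Ships a seeded synthetic methylome generator with known
    planted truth so that every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    data.table,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
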