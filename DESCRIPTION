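Package: exdna
Title: Analysis of Secreted Extracellular DNA in Yeast Fed-Batch Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking extracellular DNA (exDNA) recovered from the
    culture medium of Saccharomyces cerevisiae fed-batch runs to metabolism
    and growth inhibition. Provides stratified descriptive metrics for
    genome-mapped fragment sets (length and FPKM classes, per-chromosome
    densities, genome fraction), interval-overlap similarity metrics against
    reference fragment sets such as extrachromosomal circular DNA (eccDNA),
    gene-set extraction with Venn partitioning, KEGG-style pathway coverage
    tables, 1H-NMR spectral binning with per-mille normalization and per-bin
    growth-rate correlation fingerprinting, and a fed-batch feeding and
    growth-with-inhibitor simulator. A synthetic-data module generates every
    input type with controlled statistical structure so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
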