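Package: temeth
Title: Gene and Transposable-Element Expression Responses to Context-Specific
    DNA Methylation Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies gene and transposable-element (TE) family expression
    from multi-mapped RNA-seq alignments and relates expression changes in
    chromomethylase (CMT) and RNA-directed DNA methylation (RdDM) mutants to
    context-specific DNA methylation. Provides disjoint, exon-masked TE
    annotation construction; hierarchical unique/multi-mapped read assignment
    with family-level counting; reads-per-million normalization; a
    negative-binomial Wald test with fold-change, FDR, consistency and
    linked-locus filters; 100-bp tile methylation summaries with DMR and mCHH
    island calling; metaprofiles, proximity enrichment and
    methylation-expression correlation; TE family characterization; and a
    synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    GenomeInfoDb,
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
    tools,
    utils,
    withr
Suggests:
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
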