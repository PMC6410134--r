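Package: ervsegmap
Title: Segregating Endogenous Retrovirus Insertion Mapping from Pooled
    Mate-Pair Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects segregating endogenous retrovirus (ERV) insertions from
    pooled mate-pair sequencing of related populations. Reads that hit an
    independent ERV reference library are anchored to unique chromosomal
    positions by their mates, clustered into upstream and downstream ERV-host
    junctions, and paired into candidate insertion loci. Per-locus read
    support across pools is tested for differential presence (Freeman-Halton
    exact test or Pearson chi-square with Bonferroni control), presence
    patterns are polarized into gains and losses on the population tree, loci
    are placed in the genomic landscape relative to genes and selective-sweep
    intervals, and each locus is associated with its best-matching reference
    ERV on a phylogeny. A seeded simulator of pooled mate-pair data with
    known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ape,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
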