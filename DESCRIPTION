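Package: medseqr
Title: Differential DNA Methylation Analysis for MeD-Seq Read Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for methylation-dependent restriction enzyme
    sequencing (MeD-seq) data. Covers LpnPI-site read filtering, genome-wide
    site counting, counts-per-million normalization, read-count scoring of TSS,
    gene-body and CpG-island regions, chi-square detection of differentially
    methylated regions in region and sliding-window modes with Bonferroni or
    Benjamini-Hochberg correction, fold-change and sex-chromosome filtering,
    DMR annotation, supervised hierarchical clustering of samples, and
    Mann-Whitney validation against probe-level expression matrices. Includes a
    fully specified synthetic-data generator (genome, methylation profiles with
    injected differential regions, 32-bp LpnPI digestion fragments, 50-nt reads
    and overdispersed site counts) with ground-truth records for every injected
    effect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    ape
Config/testthat/edition: 3
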