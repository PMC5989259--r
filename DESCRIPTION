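Package: pooldiff
Title: Population-Differentiation Scans from Pooled Resequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detects candidate selection signals between pooled-resequencing
    (pool-seq) populations, as used in selective-breeding and adaptation
    studies of the Pacific oyster. Implements SNP filtering for pooled
    variant tables, allele-frequency-difference (AFD) outlier selection,
    per-site and 1-kb windowed Hudson F_ST scans with top-fraction outlier
    windows, gene mapping with flanking regions and CDS/intron/intergenic
    classification, integration of DNA- and expression-level evidence via
    Venn set logic, hypergeometric term enrichment with Benjamini-Hochberg
    correction, larval phenotype rate statistics with one-way ANOVA, and a
    synthetic pool-seq study generator with a known truth table for
    validating the whole scan end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
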