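Package: taxfunlink
Title: Taxon-Function Linkage Analysis of Shotgun Metagenome Annotation Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for comparing taxonomic and functional profiles of
    shotgun metagenomes between sample groups (e.g. male vs. female tick gut
    microbiomes) and for linking differentially abundant gene functions to the
    bacterial genera that harbor them. Implements FASTQ quality trimming and
    replicate removal, annotation-table filtering and best-hit classification,
    count aggregation at any taxonomic rank or functional level,
    median-of-ratios size-factor normalization, diversity and ordination
    statistics (rarefaction, Shannon, Bray-Curtis, ANOSIM, PCA, Venn
    partitions), two-sided Fisher's exact tests with Benjamini-Hochberg FDR
    control and Newcombe-Wilson confidence intervals, one-way ANOVA with
    eta-squared effect sizes and Tukey-Kramer post hoc tests, and the
    taxon-function linkage layer: enzyme-to-genus redundancy spectra, genus
    contribution shares, and dual-role genus partitions. A synthetic-data
    generator with planted ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    DESeq2,
    optparse
Config/testthat/edition: 3
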