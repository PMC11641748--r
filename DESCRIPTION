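Package: dualwindow
Title: Dual-Window Quantification of CRISPR Amplicon Editing with
    Genetic-Variation Artifact Detection
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the alleged editing efficiency (AEE) of CRISPR/Cas9
    amplicon sequencing experiments in a narrow (2 nt) and a wide (20 nt)
    window around the predicted cut site, derives a percentage-point
    discrepancy threshold from positive-control samples, and classifies
    discordant loci into false-editing artifact types (SNPs, divergent
    homologous alleles, repetitive/paralog co-amplification) by comparing
    sgRNA-free control and treated allele tables. Also provides a desk-scale
    GUIDE-seq-style caller for dsODN integration sites on small genomes with
    protospacer mismatch scoring, proportion statistics (arcsine transform,
    Levene test, two-level repeated-measures ANOVA), rank correlation of
    editing efficiency with normalized gene expression, and seeded simulators
    for amplicon reads, tagged genomes and count tables that emulate the data
    structure every stage assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    S4Vectors,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
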