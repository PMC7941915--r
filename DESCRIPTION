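Package: srnadeg
Title: Small RNA, Degradome and Transcriptome Analysis for Phosphate
    Starvation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, simulation-testable pipeline for nutrient-stress
    small RNA studies in plants: adapter/quality preprocessing and collapsing
    of small RNA reads, layered annotation against mature/precursor miRNA
    references and cDNA classes with isomiR classification, exact
    negative-binomial two-group differential expression with Bonferroni/FDR
    control, degradome (PARE) cleavage-profile construction and
    small-RNA target prediction under two scoring tracks (an MFE-filtered
    penalty schema and Allen-rule scoring with cleavage-peak categories and
    permutation p-values), TPM/RPKM transcript quantification with DEG
    selection, IUPAC promoter-motif scanning (P1BS, PHO element) with
    TSS-relative binning, and GO over-representation with fold enrichment.
    A synthetic-data generator with planted truth makes every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    stats,
    stringi,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    edgeR,
    jsonlite,
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
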