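Package: spetpanel
Title: Design and Validation of Targeted Single Primer Enrichment Genotyping Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for designing single primer enrichment technology (SPET)
    genotyping panels from whole-genome variant calls and for validating the
    resulting assays. Covers hard-filtering of candidate SNPs with GATK-style
    site annotations, constrained selection of budgeted target SNPs with
    probe-window and spacing rules, probe sequence extraction,
    target/accessory classification of assay calls, minor-allele-frequency
    spectrum comparison for ascertainment bias, linkage-disequilibrium
    pruning and decay, pseudo-testcross (CP) marker classification,
    Mendelian-inconsistency genotyping-error estimation with detectability
    correction, segregation-distortion and identical-locus filters, and a
    fully seeded simulator (reference, founders under Hardy-Weinberg with
    inbreeding, F1 progenies with Haldane recombination, injected errors and
    missingness) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    rlang,
    methods,
    ggplot2,
    generics,
    withr,
    jsonlite,
    yaml,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
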