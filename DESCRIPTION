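Package: ampliresist
Title: Targeted Amplicon Sequencing Genotyping of Insecticide Resistance
    Markers in Anopheles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of multiplexed, dual-barcoded amplicon
    sequencing assays used to survey insecticide-resistance mutations
    (kdr/vgsc, rdl, ace1, gste2) in Anopheles mosquitoes. Implements
    demultiplexing of pooled paired-end reads by 8-bp dual barcodes,
    quality trimming with sliding-window semantics, panel-restricted
    banded alignment, quality-filtered pileups, dual-caller SNP calling
    with allele-depth genotyping, coding-effect annotation, stratified
    allele-frequency tables with chi-square comparisons, an in-silico
    PCR-RFLP speciation assay for the An. gambiae complex, and a
    synthetic-read generator so that every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
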