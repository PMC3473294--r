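Package: mitostruct
Title: Comparative Structural Analysis of Circular Plant Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("mitostruct", "developers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing the structure of two circular plant
    mitochondrial genomes ("master circles"): deterministic seed-and-extend
    local matching, syntenic-block chaining and signed circular block
    arrangements, within-genome repeat cataloguing with sub-genomic circle
    prediction from large direct repeats, breakpoint enumeration and
    repeat-mediated rearrangement inference, unique-region extraction with
    mosaic annotation against a panel of related mitogenomes and detection of
    nested inverted-repeat integration signatures, ORF and SNP comparison with
    synonymous/non-synonymous classification, and parsimonious master-circle
    assembly from contig linkage graphs. Ships a fully ground-truthed
    synthetic-data generator so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
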