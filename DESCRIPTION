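Package: mxsplice
Title: Quantitative Profiling of Mutually Exclusive Splice Isoforms from
    Long Amplicon Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for quantifying mutually exclusive alternative
    splicing of tandem exon clusters (modelled on arthropod Dscam1) from
    barcoded long-read amplicon sequencing. Provides a combinatorial exon
    reference builder, a simulator for circular-consensus-like amplicon reads
    and qPCR crossing-point tables, barcode demultiplexing, a k-mer seeded
    banded local aligner with per-cluster variant calling under a strict
    unambiguity retention rule, per-exon differential usage testing with a
    negative binomial exact test and Benjamini-Hochberg correction, isoform
    frequency correlation, and efficiency-corrected relative expression
    analysis with a pair-wise fixed reallocation randomization test.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
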