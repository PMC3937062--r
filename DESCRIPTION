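Package: miRvine
Title: Small RNA-Seq miRNA Discovery and Two-Library Differential Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A small RNA sequencing analysis toolkit for plant miRNA
    discovery and hormone-response profiling, built around a two-library
    (treatment vs control) design. Provides adapter trimming and tag
    collapsing, length/first-nucleotide profiling, annotation-based tag
    classification, mismatch-tolerant matching against a known mature
    miRNA reference, hairpin-based novel miRNA discovery with miRNA*
    duplex evidence (maximum base-pairing secondary structure folding),
    reads-per-million normalization with five-way response
    classification (up, down, treatment-only, control-only, unchanged),
    complementarity-based target prediction with positional rules, and
    RACE cleavage-site validation against the 9th-11th nucleotide rule.
    A synthetic-data module generates toy genomes and paired libraries
    with planted ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
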