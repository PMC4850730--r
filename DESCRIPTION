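Package: exactmotif
Title: Exact Search of Degenerate DNA Motifs with Suffix-Tree Indexing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Exact occurrence search of (possibly degenerate, IUPAC-coded)
    DNA motifs in arbitrary FASTA target sequences via a per-sequence
    suffix-tree index built by naive successive suffix insertion, plus a
    companion position probability matrix (PPM) scanning mode scored
    against k-order Markov background models.  Includes an independent
    sliding-window oracle, a seeded planted-motif fixture generator,
    TSV/GFF3 hit writers and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
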