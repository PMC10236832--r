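Package: mavekit
Title: Processing and Statistical Analysis of Multiplexed Assays of Variant Effect
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end workflow for multiplexed assays of variant effect
    (MAVE) and deep mutational scanning experiments. Reads are digested into
    variant count tables under a declarative read-layout grammar (variable,
    constant, skipped, primer and UMI elements), with an ordered filter
    cascade, nearest-wildtype Hamming matching with base- or codon-level
    mutation calls, greedy collapsing of similar sequences, and UMI
    deduplication. Per-sample results are merged into a joint
    SummarizedExperiment, and variants are tested for abundance changes with
    negative-binomial quasi-likelihood or precision-weighted linear models,
    using trimmed-mean-of-M-values or wild-type-offset normalization to
    obtain absolute or wild-type-relative enrichment scores. A deterministic
    synthetic-data engine generates FASTQ libraries and count matrices with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    edgeR,
    limma,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr,
    optparse
Config/testthat/edition: 3
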