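Package: footprintr
Title: Bias-Aware Transcription Factor Footprinting from DNase-seq and
    ATAC-seq Cut Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Site-centric detection of transcription factor footprints in
    DNase-seq and ATAC-seq data at single-nucleotide resolution. Provides
    extraction and filtering of 5'-end cut-site tracks from aligned reads,
    estimation of k-mer cleavage/transposition propensities from
    deproteinized-DNA libraries, position weight matrix scanning against a
    local first-order Markov background, a two-component multinomial
    mixture model of footprint versus sequence-bias background fitted by
    expectation maximization and scored by the footprint log-likelihood
    ratio (FLR), copula-mixture irreproducible discovery rate (IDR)
    selection of reproducible footprints across replicates, cross-validated
    performance evaluation, and a fully seeded simulator that generates
    genomes, motif sites, bias tables and replicate cut-count data with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
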