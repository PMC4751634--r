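Package: adaptrim
Title: Adapter Trimming, Read Merging and Adapter Inference for Short-Read
    Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects and removes adapter contamination from single- and
    paired-end FASTQ reads using exhaustive ungapped overlap alignment with a
    configurable mismatch-rate threshold. Overlapping read pairs can be
    collapsed into a single reconstructed insert with recalculated base
    qualities, unknown adapter sequences can be reconstructed by consensus
    over read-through fragments, and pooled libraries can be demultiplexed by
    maximum-mismatch barcode comparison. Includes a paired-end read simulator
    with per-read ground truth and confusion-matrix benchmarking utilities
    (sensitivity, specificity, predictive values, Matthews correlation) for
    evaluating trimming and merging accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'adaptrim-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'adapters.R'
    'fastq-io.R'
    'alignment.R'
    'trimmer.R'
    'merger.R'
    'identifier.R'
    'demux.R'
    'simulator.R'
    'metrics.R'
    'cli.R'
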