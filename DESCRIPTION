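Package: oriscope
Title: Replication Profiling and Adaptation Analysis for Multi-Origin
    Bacterial Evolution Experiments
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing experimentally evolved bacterial
    populations whose chromosomes carry one or several replication
    origins. Computes replication-activity indices from windowed
    genome coverage (LOESS ori/ter ratio, a multi-origin peak index,
    iRep-like and peak-to-trough estimators), detects segmental
    duplications, estimates growth rates and relative fitness from
    OD600 time series with monotone fitness-trajectory smoothing,
    summarises populational variant tables with allele-frequency
    filters and codon-level effect classification, and quantifies
    transcriptome divergence as centroid distances in classical MDS
    space regressed on relative fitness. A synthetic-data module
    simulates coverage tracks under a steady-state multi-fork
    replication model, growth curves, and negative-binomial count
    matrices with expression shifts proportional to fitness gain, so
    the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    seqinr,
    jsonlite,
    optparse
biocViews: Coverage, Sequencing, Transcriptomics, ExperimentalDesign,
    Regression
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
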