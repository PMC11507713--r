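Package: dipcap
Title: Personalized Diploid Genome Training for Transcription Initiation Models
Version: 0.1.0
Authors@R:
    person("dipcap", "maintainers", email = "dipcap@example.org", role = c("aut", "cre"))
Description: Tools for studying whether sequence-to-function models of
    transcription initiation benefit from training on personalized diploid
    genomes rather than a single reference genome. Provides a two-hot
    encoding of unphased diploid sequence, a compact convolutional
    profile-plus-quantity network with a multiscale (cosine profile +
    log-quantity) loss, chromosome-fold ensemble training with
    variant-masking and individual-subsampling ablations, initiation-QTL
    effect scoring by the L2 norm between genotype-averaged coverage
    tracks, reporter-assay style variant benchmarking with bootstrap
    precision-recall comparisons, and a synthetic diploid panel generator
    with planted quantity and directionality variant effects so the whole
    analysis runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
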