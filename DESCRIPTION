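Package: scNOMe
Title: Joint Analysis of Single-Cell Methylation, Chromatin Accessibility
    and Transcription from NOMe-Seq Bisulfite Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for single-cell NOMe-seq experiments in which a GpC
    methyltransferase labels accessible chromatin prior to bisulfite
    sequencing, so that endogenous CpG methylation and chromatin
    accessibility are read out from the same molecule. The package
    separates the two signals by trinucleotide context, estimates
    per-site and per-feature rates with beta-binomial shrinkage,
    tests for coupling between molecular layers with coverage-weighted
    Pearson correlations and Benjamini-Hochberg FDR control, models
    single-cell accessibility profiles around transcription start sites
    with Bernoulli basis-function regression and EM mixture clustering,
    orders cells along a diffusion pseudotime, and ships a synthetic
    single-cell NOMe-seq generator with full ground truth so every
    analysis step can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
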