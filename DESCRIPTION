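Package: chromstates
Title: Window-Based Chromatin-State Analysis of Enhancers and
    Heterochromatin Across Differentiation Stages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for histone-mark ChIP-seq window analysis
    across cell-differentiation stages: sliding-window tag counting with
    fragment-shift, library-size normalization, pseudo-count log2
    enrichment over input, replicate averaging, threshold-and-merge
    region calling; classification of promoter-distal H3K4me1 regions
    into active, primed and poised enhancers from H3K27ac and H3K27me3;
    two-pass assignment of enhancers to their closest promoters;
    cross-stage enhancer-state transition analysis at fixed coordinates;
    and segmentation of H3K9me2 log2 enrichment into heterochromatin
    domains with a two-state Gaussian-emission hidden Markov model
    (Baum-Welch training, Viterbi decoding). Includes a synthetic-data
    generator with ground-truth chromatin states so the complete
    analysis runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    rtracklayer,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
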