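Package: brainfp
Title: Brain-Network Fingerprinting from EEG via Symbolic Transfer Entropy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for participant identification from multichannel EEG
    recordings through directed functional connectivity. Signals are
    band-pass filtered, first-differenced, tercile-symbolized and embedded
    into ordinal words; pairwise symbolic transfer entropy yields a 64x64
    directed coupling matrix per task and event. Directed brain networks
    are built as minimum spanning arborescences (Chu-Liu/Edmonds), and the
    complex eigen-spectrum of each coupling matrix, z-score normalized and
    coarse-grained onto a two-dimensional grid, serves as a per-participant
    fingerprint. A spectrum-distribution set scoring classifier identifies
    participants by histogram intersection against per-participant
    reference grids, with supporting Euclidean-distance summaries, a
    two-sample z-test, a balanced two-way ANOVA, and a vector-autoregressive
    synthetic cohort generator for end-to-end validation without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
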