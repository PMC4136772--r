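Package: lrdalign
Title: Short-Read Alignment and Reference-Free Clustering Under Local Rank Distance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns short DNA reads against reference genomes under Local
    Rank Distance (LRD), a rank-based string dissimilarity that sums the
    capped positional offsets between identical k-mers of two sequences.
    Provides the exact sliding-window aligner, a fast approximate aligner
    built on a per-read positional inverted index with candidate-window
    skipping and early abort, a wgsim-style read simulator with ground-truth
    coordinates, a nearest-genome scoring rule for placing an unknown
    organism in a labelled genome collection (with leave-one-out
    evaluation), and threshold-sweep evaluation utilities
    (precision/recall, ROC/AUC, F-beta, true-positive versus false-negative
    sequence-distance summaries). A command-line front end binds the
    pieces together.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
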