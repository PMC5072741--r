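Package: editscan
Title: String-Kernel Prediction of A-to-I RNA Editing Sites from DNA Sequence
Version: 0.1.0
Authors@R:
    person("editscan", "developers", email = "editscan@example.org",
           role = c("aut", "cre"))
Description: Predicts adenosine-to-inosine (A-to-I) RNA editing events from
    genomic DNA sequence alone. Fixed-length, adenine-centered sequence
    contexts around known editing sites are compared with a combined,
    length-normalized Levenshtein/Hamming string distance, mapped into a
    Gaussian-type string kernel, and classified with maximal-margin
    classifiers (binary and one-class) trained on the precomputed kernel.
    Includes context extraction from FASTA genomes, background (negative)
    sampling, greedy identity-based redundancy filtering, oversampled
    stratified cross-validation with imbalance-aware metrics (MCC, G-mean,
    ROC/AUC), a mismatch-tolerant seed scanner with a two-stage
    (one-class then binary) caller for whole-sequence screening, a
    synthetic-benchmark generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
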