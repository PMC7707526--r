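Package: negbench
Title: Negative Training Data Benchmarks for Regulatory Sequence Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to study how the construction of negative training data
    affects sequence-based models of regulatory activity. Implements
    k-mer-count-preserving sequence shuffling via random Eulerian paths on
    de Bruijn graphs, GC- and repeat-matched sampling of genomic background
    windows (tolerance and histogram matching), gapped k-mer featurization
    with a linear large-margin classifier, evaluation on chromosome
    hold-out, tissue-specificity and quantitative activity tasks, and
    sequence-composition diagnostics (genome k-mer frequency Z-scores,
    motif-density scans, GC distributions). A synthetic-genome simulator
    with planted transcription-factor motif elements makes the full
    pipeline reproducible without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Matrix,
    Rcpp,
    glmnet,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
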