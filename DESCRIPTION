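Package: crtscreen
Title: Machine-Learning Screening of Bibliographic Citations for Cluster Randomized Trial Reports
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Trains and applies an ensemble citation screener that decides,
    from a bibliographic record alone (title, abstract, keywords, subject
    headings), whether an article reports a cluster randomized trial.  The
    ensemble averages the probabilities of two convolutional text classifiers
    (one on whole-word skip-gram embeddings, one on subword embeddings) and a
    TF-IDF radial-basis support vector classifier, and applies a
    sensitivity-targeted decision threshold.  Includes corpus-trained
    embedding and convolutional trainers, class-imbalance handling,
    hyperparameter search (random and tree-structured Parzen estimator
    samplers), screening-specific evaluation metrics (AUC with stratified
    bootstrap intervals, number needed to screen and read, per-class term
    associations), bibliographic readers (CSV, MEDLINE tagged, RIS), and a
    synthetic citation-corpus generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    e1071,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
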