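Package: labnorm
Title: Laboratory Indicator Name Normalization with Candidate Recall,
    Sequence-Pair Classification and Active Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Normalizes heterogeneous laboratory-indicator names (as found
    across hospital electronic health record systems) onto a designated
    standard vocabulary. A character-level tf-idf recall stage retrieves a
    small candidate set of standard indicators for every non-standard name,
    an enhanced sequential inference model (ESIM) sequence-pair classifier
    decides synonymy for each candidate pair, and a pool-based active-learning
    loop with least-confidence, Shannon-entropy and gini-index selection
    strategies reduces the annotation effort needed to train the classifier.
    Includes edit-distance, bag-of-words and BM25 retrieval baselines,
    Recall/MRR and precision/recall/F1 evaluation, and a synthetic corpus
    generator that emulates translation variants, habit rewordings and
    abbreviation noise so the whole pipeline can be exercised without access
    to private hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    stringi,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
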