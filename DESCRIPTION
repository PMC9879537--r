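Package: crossexpress
Title: Cross-Species Expression Score Classification and Orthogroup Fractionation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns an Expression Score (ES) to interspecific gene pairs by
    training gradient-boosted decision-tree classifiers on concatenated raw
    read-count expression profiles, with out-of-fold re-classification of
    training pairs and median aggregation over randomized iterations.
    Fractionates orthogroups into expression-consistent "expresso-groups" by
    thresholding ES-weighted bipartite graphs, and benchmarks against a
    grouped-sample pseudo-Euclidean distance baseline with median-of-ratios
    size-factor normalization and replicate resampling. Includes a
    negative-binomial paired-species expression simulator with planted
    conserved and diverged ortholog pairs, ROC and precision-recall
    evaluation utilities, expression-breadth stratification,
    sample-downsampling stability checks, and a Needleman-Wunsch protein
    identity utility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    DESeq2,
    igraph,
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
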