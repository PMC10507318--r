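Package: hairpinlearn
Title: Machine Learning Experiments on RNA Strand Complementarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates synthetic RNA hairpin (stem-loop) datasets in which the
    two strands of the stem are either fully Watson-Crick complementary or not,
    and studies how well small neural networks and classical machine-learning
    baselines recognise full complementarity. Provides the data generator
    (controllable strand length, loop length, dataset size, positivity rate and
    mislabelling probability, with disjoint train/test partitions of the
    sequence space), four small neural architectures (multi-layer perceptron,
    multi-head self-attention, bidirectional LSTM and convolutional network)
    with capacity controlled by a fixed hyper-parameter ledger, an alpha-weighted
    binary cross-entropy training loop, threshold-based accuracy evaluation,
    classical baselines (k-nearest neighbours, support vector machine, decision
    tree, random forest), and experiment-grid orchestration with tidy outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings,
    randomForest,
    e1071,
    rpart,
    class
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
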