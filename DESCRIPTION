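Package: plcell
Title: Partial Label Learning for Single-Cell Transcriptomic Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classify single-cell transcriptomic profiles from partially
    annotated training data, where each ambiguous cell carries a set of
    candidate labels exactly one of which is correct. Provides prototype-based
    (linear and neural-network), max-margin, logistic-regression, nearest
    neighbour and tree-ensemble classifiers, trained by two alternating
    label-inference/refit algorithms (iterative refinement learning and
    iterative full retraining), with hierarchy-aware margin rescaling along a
    cell-lineage tree. Includes a tree-structured negative-binomial count
    simulator for differentiation trajectories, scenario generators that
    control label overlap, candidate-set size and tree-distance intervals,
    and a cut/cross-validation benchmarking protocol with paired significance
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    randomForest,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
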