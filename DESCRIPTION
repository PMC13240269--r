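Package: netstab
Title: Stability-Driven Network Feature Selection for EEG Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for classifying subjects from multichannel
    EEG via band-limited functional connectivity and brain-network topology.
    Computes phase-locking value and magnitude-squared coherence matrices per
    epoch and frequency band, derives weighted graph metrics (strength,
    clustering, global efficiency, characteristic path length) and region-pair
    connectivity summaries, ranks features by a fold-wise stability score
    (mean importance over its across-fold dispersion), and evaluates SVM and
    random-forest classifiers under nested subject-wise cross-validation with
    subject-level aggregation, bootstrap confidence intervals, and permutation
    and Shapley attribution. Includes a seeded synthetic-EEG generator with
    von Mises phase coupling so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    igraph,
    e1071,
    randomForest,
    pROC,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
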