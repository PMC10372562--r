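Package: fedsilo
Title: Cross-Silo Federated Learning Simulator with Exact Aggregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates star-topology cross-silo federated analyses on a
    single machine: one coordinator and several data-holding participants
    execute chained federated applications (cross-validation, normalization,
    model training, evaluation) over an in-memory message bus with byte-size
    accounting.  Implements exact one-shot federated linear regression via
    Gram-matrix aggregation, iterative federated logistic regression via
    Newton-Raphson with summed gradients and Hessians, ensemble-merging
    federated random forests with sample-proportional tree allocation,
    FedAvg training of multilayer perceptrons, federated Kaplan-Meier
    curves and log-rank tests from aggregated event tables, and additive
    secret sharing over a fixed-point prime ring so the coordinator learns
    only global sums.  A synthetic-data module generates classification,
    regression, and survival datasets with configurable non-IID label-skew
    partitioning so every federated application is testable against its
    centralized counterpart without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse,
    withr
Config/testthat/edition: 3
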