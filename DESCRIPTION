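Package: microstnet
Title: Two-Stream Spatio-Temporal Graph Forecasting of Microbial Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forecasts longitudinal taxon abundance profiles with a
    two-stream spatio-temporal graph convolutional network fused with a
    stacked LSTM branch. Builds taxon-taxon co-occurrence networks from
    abundance tables (Spearman rank correlation, permutation p-values,
    Benjamini-Hochberg correction, significance thresholding, symmetric
    adjacency normalisation), standardises and windows the series into an
    abundance stream and a first-difference change stream, trains the
    network and its ablation variants (recurrent-only, graph-only) with
    best-validation-MAE checkpointing, and produces recursive one-step and
    multi-step forecasts on the original abundance scale. Includes a
    graph-coupled vector-autoregressive simulator with a closed-form
    optimal forecast error so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
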