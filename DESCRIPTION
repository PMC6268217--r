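Package: vsmvi
Title: Variable-Interaction Subset Selection for QSAR Regression Models
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Best-subset descriptor selection for multiple linear regression
    QSAR models via a pool-based variable-interaction search (VSMVI):
    exhaustive screening of low-order descriptor subsets followed by
    interaction-driven extension of a fixed-capacity pool of optimal
    subsets, gated by inter-descriptor correlation and a minimum training
    fit, and scored by leave-multiple-out Monte-Carlo cross-validation.
    Includes descriptor-matrix preselection filters (near-constant, highly
    inter-correlated and zero-inflated columns), LOO and leave-multiple-out
    cross-validation summaries, y-randomization chance-correlation testing
    with the c r2p statistic, and a leverage-based applicability domain
    with Williams-plot outlier classification. Ships deterministic
    synthetic-fixture generators so the whole toolkit is testable without
    external descriptor data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
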