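Package: cbnDiff
Title: Structural Difference Estimation for Causal Bayesian Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Estimates the structural difference between two causal
    Bayesian networks learned from two datasets of possibly unequal
    sample size. Implements three edge-difference estimators (naive,
    bootstrap, and equal-sample-size resampling), a linear-Gaussian
    structural-equation simulator that produces paired networks with a
    controlled number of differing edges and unit marginal variances,
    constraint-based (PC) and score-based (greedy BIC) structure
    discovery backends, evaluation of edge differences as a binary
    classification problem (AUCROC, AUPR, cross-entropy, F1-optimised
    threshold metrics, and Cohen's f-squared effect sizes), a
    simulation-grid experiment runner, and a variable-permutation
    protocol for benchmarking on real tabular data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), igraph, pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
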