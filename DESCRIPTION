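Package: dids
Title: Detection of Imbalanced Differential Signal in Expression Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects features (genes, probes, proteins) that are aberrantly
    expressed in only a subgroup of a case group relative to all controls.
    Implements the DIDS score (sum of excess expression beyond the control
    extremum, passed through a sqrt, quadratic or tanh scoring function)
    with an analytical exact permutation p-value, alpha filtering and score
    ranking in both the up- and down-regulation directions. Also provides
    the outlier statistics COPA, OS, ORT and MOST, classical two-sample
    tests (t, Mann-Whitney, Kolmogorov-Smirnov), a synthetic-data generator
    for spike-in reporter genes, and a simulation harness that benchmarks
    power and positive predictive value over grids of effect size and
    aberrant-sample fraction using empirical null distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
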