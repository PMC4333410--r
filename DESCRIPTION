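Package: rewirepath
Title: Population Statistics and Transcriptome Trajectory Analysis of
    Adaptation to Gene Rewiring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing how gene-rewired Escherichia coli
    populations adapt to nutrient starvation. Implements flow-cytometry
    event gating and reporter-ratio (GFP bias) population statistics,
    exponential growth-rate estimation, common-mean normalization and
    filtering of log-scale expression matrices, rank-product differential
    expression with permutation-based false-positive-rate estimation,
    principal-component trajectory analysis of transcriptional-change
    matrices (total-least-squares path fitting, normalized-distance
    projection, growth correlation, loading tails), binomial gene-set
    enrichment with Bonferroni correction, and K-means clustering of
    change profiles. A seeded synthetic-data generator plants ground
    truth (fate classes, a one-dimensional expression trajectory,
    differential genes, enriched sets) so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
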