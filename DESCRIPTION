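Package: lfqatlas
Title: Spatiotemporal Analysis of Label-Free Quantitative Proteomic Atlases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing developmental label-free quantification (LFQ)
    proteomic atlases sampled over brain regions and stages: differential
    abundance with pooled-variance t-tests and Bonferroni control, one-vs-rest
    ROC-AUC marker detection, intensity-weighted composition trends,
    inter-regional dissimilarity and distance statistics, protein emergence
    calling, per-day rates of change, gene-set trajectories, fuzzy c-means
    trend clustering, hypergeometric over-representation analysis,
    cross-species ortholog correlation conservation classes, and six-type
    RNA/protein fold-change concordance typing. Includes a synthetic-data
    generator that emulates zero-inflated log-normal LFQ intensities with
    planted stage, region, marker, emergence, conservation and concordance
    structure so every stage of the pipeline is testable without external
    data.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    e1071,
    fgsea,
    jsonlite,
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
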