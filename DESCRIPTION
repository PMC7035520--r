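Package: netpharm
Title: Network Pharmacology Screening and Bioassay Analytics for Herbal
    Compound Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for network-pharmacology screening of
    herbal compound libraries and for the bench-assay statistics used to
    validate screening hits. Filters compounds on signed-probability absorption
    predictions (human intestinal absorption, Caco-2) and a composite
    CYP450-inhibition score weighted by per-isoform predictive accuracy;
    builds compound-target bipartite networks with degree-based hub
    extraction, target-disease-group networks and Cytoscape-compatible
    exports; and implements the downstream validation math: MTT inhibition
    rate, four-parameter log-logistic IC50 fitting, 2^-ddCt relative
    expression, Annexin V/PI quadrant gating, JC-1 depolarized-fraction
    estimation and a permutation dose-trend test. Ships seeded synthetic-data
    generators with planted ground truth for every input so the whole pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    withr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    igraph,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
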