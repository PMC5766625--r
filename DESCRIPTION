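Package: paircoex
Title: Weighted Co-Expression Network Analysis for Paired Case-Control Designs
Version: 0.1.0
Authors@R:
    person("Maintainer", "paircoex", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds weighted gene co-expression networks (absolute Pearson
    similarity, soft-thresholded adjacency, topological overlap) and detects
    co-expression modules for two-condition paired designs, where each subject
    contributes one case and one matched control sample. Module eigengenes and
    individual genes are related to condition with a random-intercept linear
    mixed-effects model, yielding paired-design gene significance and module
    significance. Includes a mixture-correlation identity showing pooled
    Pearson correlation remains a valid co-expression measure under pairing,
    sample-level quality control with pair-consistent exclusion, hub detection
    with Cytoscape-ready exports, a synthetic paired-data generator with
    planted modules, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    igraph,
    withr
Config/testthat/edition: 3
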