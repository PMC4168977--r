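Package: snowflaker
Title: Geometry, Fragmentation and Evolution of Snowflake Yeast Clusters
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models the cellular geometry of experimentally evolved
    "snowflake" yeast: clusters are lineage trees in which daughter cells
    stay attached to their mothers after budding. Provides the lineage-tree
    data model with degree-capped, shell-volume-limited synchronized growth;
    closed-form and recursive analytics for branch-size series (generalized
    Fibonacci recursions) and concentric-shell packing constraints with
    first-overflow generations; exact enumeration of expected offspring-size
    asymmetry under apoptosis-driven link severance; an agent-based
    population simulator of cluster growth, death and fragmentation; a
    dynamic-programming model of optimal cluster division under settling
    selection; and a mutation-selection transfer simulation in which
    per-cell death probabilities evolve under diameter-weighted settling
    selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
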