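Package: ccnet
Title: Co-Consumption Network Analysis of Dietary Intake
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds co-consumption networks (CCNs) from participant-by-food-group
    intake matrices: split-half resampling validation of positive Spearman
    correlations, quartile binarization and consumption scores, label-propagation
    community detection with consensus over random restarts, hypergeometric
    assignment of participants to healthy/unhealthy modules, steatosis grading
    from controlled attenuation parameter (CAP) scores, group-differential and
    age-trend networks, and chi-square/FDR association tests for module-related
    cliques. Includes a synthetic cohort generator with planted correlation
    blocks for ground-truth recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
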