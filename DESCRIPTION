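Package: phytoscore
Title: Multi-Region Quality Evaluation of Medicinal Fruit Panels
Version: 0.1.0
Authors@R: person("phytoscore", "developers", role = c("aut", "cre"),
    email = "phytoscore@example.org")
Description: A tested pipeline for evaluating the quality of medicinal plant
    material sampled across production regions: descriptive statistics of
    mineral-element and phytochemical panels, one-way ANOVA with Duncan's new
    multiple range test and compact letter displays, Pearson correlation
    matrices with significance stars, Mantel tests of matrix association
    (Bray-Curtis / Euclidean), complete-linkage hierarchical clustering,
    correlation-matrix principal component analysis, and a variance-weighted
    comprehensive quality score used to rank production regions. Includes a
    synthetic generator of replicate-level measurement tables with
    configurable region-mean ranges, within-region coefficients of variation
    and target correlation structure.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
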