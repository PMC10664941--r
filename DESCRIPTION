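Package: serprisk
Title: Spatial Risk Indices and Cluster Profiling for Snakebite Epidemiology
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for multi-component spatial risk analysis of snakebite
    envenoming at the census enumeration-area (EA) scale. Builds composite
    hazard, exposure, susceptibility and healthcare resource-scarcity indices
    by cosine-similarity ranking of z-standardized EA covariates against a
    hypothetical worst-case reference, partitions EAs into risk profiles with
    seeded k-medoids clustering scored by the Calinski-Harabasz pseudo
    F-statistic, stacks species-distribution suitability surfaces into a
    venomous-snake richness layer via max(sensitivity + specificity)
    thresholds, estimates travel time to treating health facilities over a
    friction surface by exact multi-source Dijkstra, and computes registry
    descriptive statistics (tabulations, relative risk, chi-squared with
    Cramer's V, log-linear elevation-incidence rate fits). A seeded
    synthetic-landscape generator with planted archetypes and effect sizes
    makes the whole pipeline testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
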