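Package: chondrorisk
Title: Trait-Based Extinction-Risk Analysis for Chondrichthyan Fishes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for global extinction-risk analysis
    of sharks, rays, and chimaeras. Provides validated I/O for species
    trait/status tables, IUCN Red List category tabulation and family-level
    binomial threat tests, binomial GLM/GLMM modelling of threat correlates
    with nested taxonomic random intercepts, AICc model comparison and
    Akaike weights, ROC-threshold imputation of Data Deficient species'
    status and category apportioning, per-cell richness/threat/
    irreplaceability scoring on equal-area grids, fisheries landings trend
    statistics, and seeded synthetic-data generators with known ground
    truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
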