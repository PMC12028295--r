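Package: ecmassembly
Title: Neutral and Niche Assembly Analysis for Ectomycorrhizal Fungal
    Communities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify neutral versus niche assembly in
    ectomycorrhizal (EcM) fungal communities from amplicon sequence
    variant (ASV) count tables. Implements ASV-table filtering and
    rarefaction, a GAM-based abundance-occupancy neutral model with a
    pseudo-R-squared fit statistic and a migration-rate estimate,
    alpha-diversity contrasts with assumption-driven test selection,
    Hellinger/Bray-Curtis beta diversity with NMDS, PERMANOVA and
    ANOSIM, and random-forest indicator-taxon detection with log
    response-ratio effect sizes. A synthetic-community simulator with
    known dispersal-structured (neutral) and host-filtered (niche)
    regimes provides ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    vegan,
    randomForest,
    car,
    jsonlite,
    stats,
    utils
Suggests:
    biomformat,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
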