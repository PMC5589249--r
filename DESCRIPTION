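Package: threatmapr
Title: Spatially Explicit Multi-Threat Assessment for Tree Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Species-specific, spatially explicit assessment of multiple
    threats (overexploitation, overgrazing, fire, cotton production, mining
    and climate change) to tree species on a common raster grid. Combines
    AUC-weighted ensemble species distribution models, cultural-consensus
    weighting of expert survey responses, per-threat intensity layers with
    ordinal threat-magnitude classification, and a rule-based combiner
    producing per-species combined threat maps, hotspot and richness maps,
    and per-class area summaries. Includes a synthetic data generator that
    emulates every pipeline input so the whole analysis is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    rpart,
    ranger,
    xgboost,
    e1071,
    MASS,
    class,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
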