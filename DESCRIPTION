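Package: gutclock
Title: Gut Microbiome Aging Clocks from Multi-View Metagenomic Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and interprets gut microbiome aging clocks from paired
    species and metabolic-pathway relative-abundance profiles. Provides a
    synthetic generator for sparse compositional two-view data with planted
    age markers, readers for merged MetaPhlAn- and HUMAnN-style tables,
    diversity and confounder-adjusted PERMANOVA summaries, recursive
    cohort elimination to remove region-age confounding, a heterogeneous
    stacked ensemble age regressor that exploits unpaired single-view
    samples, accumulated local effects (ALE) interpretation with
    directional marker selection, and downstream association of predicted
    age and its residuals with frailty and disease phenotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    glmnet,
    ranger,
    xgboost,
    rpart,
    e1071,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
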