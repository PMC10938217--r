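Package: cadmb
Title: Gut Dysbiosis Index and Imidazole Propionate Analysis for HIV
    Coronary Artery Disease Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for the downstream microbiome
    analysis of cross-sectional HIV cohorts relating gut dysbiosis and
    circulating imidazole propionate (ImP) to obstructive coronary artery
    disease. Implements rarefaction, alpha diversity (observed ASVs,
    Shannon, Faith phylogenetic diversity), Bray-Curtis beta diversity with
    PCoA and PERMANOVA, LEfSe-style differential abundance, a log-ratio
    CAD-related dysbiosis index with quartile analyses, bootstrap
    random-forest ranking of taxa predictive of plasma ImP, a priori
    adjusted logistic models with ROC comparison, and bootstrap mediation
    analysis. Ships a synthetic cohort generator emulating the study design
    (three CAD groups, compositional 16S counts with planted index-genus
    effects, producer-coupled ImP, confounded covariates) so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    ape,
    vegan,
    picante,
    ranger
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
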