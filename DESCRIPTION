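Package: transkingdom
Title: Trans-Kingdom Analysis of Gut Bacterial-Fungal Communities and
    Their Metabolic and Behavioral Correlates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical pipeline for paired 16S/ITS amplicon studies of the
    gut microbiome: alpha diversity (Sobs, Chao1, Shannon, Gini-Simpson) and
    the fungal-to-bacterial richness ratio (ITS/16S), Bray-Curtis and
    unweighted UniFrac dissimilarities with principal coordinates analysis
    and PERMANOVA, Wilcoxon/FDR differential-abundance screening and a
    LEfSe-style linear-discriminant effect-size procedure, trans-kingdom
    Spearman correlation networks with summary parameters (nodes by kingdom,
    signed edges, relative connectedness, clusters), OPLS-DA discriminant
    modelling of metabolite profiles with VIP scores and permutation
    validation, module-level microbiome-metabolome partial correlations
    adjusted for a covariate, fecal-microbiota-transplant engraftment
    accounting, and composite behavioral z-scores. Includes a seeded
    synthetic-cohort generator with planted cross-kingdom coupling, fungal
    richness deficits, metabolite loadings and behavioral effects so that
    every stage of the pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    vegan,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
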