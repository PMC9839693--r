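Package: paircohort
Title: Paired Case-Control Microbiome and Metabolome Analysis with
    Random-Pairing Permutation Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for paired case-control studies of the gut microbiome and
    metabolome in which each case (patient) may have zero, one or several
    eligible control (cohabitating relative) samples. Implements eligible-pair
    enumeration under a collection-date window, a random-pairing permutation
    paired t-test that aggregates statistics across repeated random
    one-relative-per-patient draws, OTU-table diversity analysis (rare-feature
    filtering, rarefaction, inverse Simpson, richness, shared-OTU fractions,
    Bray-Curtis), enterotype discovery by partitioning around medoids with
    silhouette-based model selection, PERMANOVA and beta-dispersion on
    distance matrices, exact 2x2 association testing, metabolite
    concentration preprocessing with PLS-DA validation, and longitudinal
    mouse-colony analyses (pathology scoring, gut transit, divergence
    trajectories). Includes synthetic cohort and mouse-colony generators that
    emulate the statistical structure of such studies so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    cluster,
    vegan,
    mclust,
    mixOmics
Config/testthat/edition: 3
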