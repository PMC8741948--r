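Package: milletmyco
Title: Root Mycobiome Diversity, Trophic Guilds and Co-Occurrence Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of fungal ITS metabarcoding data from plant
    roots, built around the comparison of cultivated and wild pearl millet
    root mycobiomes. Provides rarefaction normalization and alpha-diversity
    indices, Bray-Curtis dissimilarities with non-metric multidimensional
    scaling, permutation-based community statistics (PERMANOVA, multivariate
    dispersion homogeneity, environmental vector fitting), FUNGuild-style
    trophic-guild aggregation with soil-property correlations,
    prevalence-based core-mycobiome extraction, and FDR-thresholded Spearman
    co-occurrence networks with topology metrics and hub-taxon calling. A
    Gaussian-copula negative-binomial simulator generates OTU tables with
    planted correlation blocks, hubs, site and plant-type effects and
    soil-guild correlations, so every stage can be validated against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
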