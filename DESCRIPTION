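Package: geothermflora
Title: Phylogenetic Clustering, Taxon Enrichment and Soil Gradients for
    Geothermal Plant Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing vascular-plant communities along geothermal
    soil gradients: hypergeometric over- and under-representation of taxa
    within species groups, the net relatedness index (NRI) computed against a
    pair-subsampling null, permutation tests for between-zone
    species-composition overlap, Spearman and Hoeffding screening of edaphic
    factors limiting species cover, soil weathering and temperature-gradient
    indices, and a seeded synthetic-data generator that emulates the
    statistical structure of such surveys so the whole pipeline can be
    exercised end to end without field data.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    phytools,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
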