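Package: defauna
Title: Reconstructing Mammal Defaunation from Stacked Distribution Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct regional defaunation of medium- to
    large-bodied mammal assemblages by contrasting maximum-entropy
    historical species distribution models against inverse-distance-weighted
    contemporary assemblage surfaces. Includes a planar raster and
    hexagonal-grid spatial toolkit, a virtual-species world simulator with a
    known logistic extirpation process, assemblage downsizing and range-loss
    metrics, Gower/PCoA convex-hull functional richness, and gradient-boosted
    driver models with exact interventional Shapley attribution.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    cluster,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
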