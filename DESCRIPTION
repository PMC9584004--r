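Package: charcoalscape
Title: Detection and Landscape Analysis of Relic Charcoal Hearths from
    High-Resolution Terrain Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An object-based pipeline for mapping relic charcoal hearths
    (RCHs) on high-resolution digital terrain models and relating them to
    forest history. Provides terrain derivatives (slope, roughness, heat
    load, wetness and position indices, distances and kernel density),
    grayscale morphological closing of the slope raster, seeded region
    growing segmentation, per-object zonal statistics and shape indices,
    random-forest classification with fivefold cross-validated accuracy
    and Cohen's kappa, inverse distance weighting of species proportions
    with leave-one-out accuracy, historical-to-current composition change
    maps, the Brillouin diversity index, and redundancy analysis with
    Monte Carlo permutation testing. A synthetic-landscape generator
    produces ground-truthed hillslope terrain with embedded hearth
    platforms and confuser landforms, charcoal taxon counts, and forest
    plot tables so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    graphics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
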