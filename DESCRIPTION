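Package: canopycool
Title: Urban Tree-Canopy Greening Scenarios and Heat Mitigation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Spatially explicit simulation of urban greening scenarios and
    their heat-mitigation potential at the agglomeration scale. Refines a
    coarse land-use/land-cover raster by fine-scale tree-canopy and building
    cover, generates stochastic tree-canopy scenarios under random,
    clustering and scattering spatial allocation strategies, simulates
    night-time air temperature with a shade/evapotranspiration/albedo
    cooling-capacity model including park cooling and air-mixing terms,
    quantifies canopy pattern with landscape metrics (PLAND, AREA_MN,
    SHAPE_MN, ED), and tabulates population exposure to temperature
    thresholds. Ships a synthetic-city generator so the whole pipeline is
    reproducible without proprietary input data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
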