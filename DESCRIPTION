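Package: mangromorph
Title: Bio-Morphodynamic Simulation of Mangrove Estuaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduced-complexity bio-morphodynamic simulator for back-barrier
    estuaries colonized by mangroves (Avicennia marina). Couples depth-averaged
    tidal flow with vegetation-modified hydraulic roughness (Baptist
    formulation), cohesive and non-cohesive sediment transport
    (Partheniades-Krone mud exchange, capacity-based sand transport with
    transverse-slope correction), morphologically accelerated bed updating with
    vertical stratigraphy bookkeeping, and a seasonal mangrove life cycle
    (colonization, diameter growth, competition, self-thinning, removal).
    Includes a scenario engine reproducing catchment mud-supply and
    mangrove-removal management experiments over centuries, and landscape
    metrics (accommodation space, muddy-region fraction, mangrove coverage,
    relative basin area above mean sea level, sediment yield over tidal prism).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    deSolve,
    knitr,
    rmarkdown
Config/testthat/edition: 3
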