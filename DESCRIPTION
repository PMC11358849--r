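Package: oxisim
Title: Monte Carlo Simulation of Skin-Tone Effects in Pulse Oximetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxel-based Monte Carlo photon transport through a four-layer
    finger phantom (epidermis, dermis, two arteries, bone) for studying how
    epidermal melanin biases pulse-oximeter readings. Provides a tissue
    optical-property database driven by chromophore composition (melanin,
    water, oxy- and deoxyhemoglobin), a compiled Henyey-Greenstein transport
    kernel with implicit-capture weighting and Russian roulette, and the
    downstream photoplethysmography analysis: perfusion index, ratio of
    ratios, attenuation decomposition, optical path length and penetration
    depth statistics, and SpO2 calibration-curve comparisons across
    transmission and reflection geometries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    nortest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
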