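Package: phasetomo
Title: Single-Distance X-Ray Phase-Contrast Tomography Simulation and
    Stain Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forward simulation and analysis of propagation-based X-ray
    phase-contrast tomography (XPCT) in parallel-beam geometry. Provides
    X-ray optical-constant arithmetic (wavelength, Fresnel number,
    delta/beta ratios, attenuation to atom number-density conversion),
    layered phantom generation, a Fresnel forward model with detector
    noise, projection-domain corrections (flat/dark normalization,
    hot-pixel repair, rotation-axis estimation, wavelet-FFT ring
    filtering), single-distance CTF and Paganin phase retrieval,
    Ram-Lak filtered backprojection, and a histogram-based workflow that
    converts the excess attenuation of heavy-atom stained tissue into
    stain number density, mass density, and mean interatomic distance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    tiff
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
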