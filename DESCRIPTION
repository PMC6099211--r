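Package: mammodose
Title: Monte Carlo Internal Breast Dosimetry for Mammography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Photon Monte Carlo simulation of local dose deposition in
    voxelized homogeneous and anthropomorphic compressed-breast phantoms
    under a clinical mammography geometry (heel-weighted collimated point
    source, compression paddle, carbon-fiber support table), together with
    mammographic x-ray spectrum modelling and half-value-layer tuning,
    TLD/MOSFET/radiochromic-film calibration models with combined standard
    uncertainty propagation, depth-dose and 2D dose-map analysis, and
    average glandular dose comparison between heterogeneous and
    homogenized breast models. Transport uses Woodcock (delta) tracking
    in the kerma approximation with history-by-history variance
    estimation; bundled elemental photon interaction coefficients cover
    1-40 keV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
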