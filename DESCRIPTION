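Package: saxsim
Title: Simulation of Isotropic 2D Small-Angle X-Ray Scattering Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates two-dimensional small-angle X-ray scattering (SAXS)
    images on virtual photon-counting detectors (Pilatus, Eiger) from
    calculated one-dimensional scattering curves on absolute scale. Photon
    arrival is modelled as a Poisson process: event radii are drawn by
    inverse-transform sampling from the area-weighted intensity
    distribution, directions uniformly, and events are quantized onto the
    detector pixel grid with module gaps. Includes beamstop/gap mask
    generation (FIT2D .MSK), angular axis calibration, TIFF/EDF image
    output, radial averaging with Poisson error propagation, background
    subtraction and concentration scaling, and statistical validation of
    simulated data via the reduced chi-squared test and the case-0
    Anderson-Darling normality test on standardized residuals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
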