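Package: traitspectrum
Title: Trait-Resolved Community Size Spectrum Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates size-structured marine communities with a
    McKendrick-von Foerster equation extended by a growth-diffusion term.
    Four dynamic functional groups (zooplankton, low- and high-activity
    cephalopods, fish) feed on each other and on a static phytoplankton
    size spectrum through lognormal size-selection kernels whose
    predator-prey mass ratio (PPMR) may be constant or increase
    allometrically with predator mass. Includes factorial experiment
    builders contrasting trait-resolved cephalopod parameterizations
    against fish-like controls, and emergent ecosystem metrics: biomass,
    production, turnover time, biomass stability (1/CV), size-spectrum
    slope and intercept, realised PPMR and trophic position curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
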