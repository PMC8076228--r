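Package: suturesim
Title: Simulation and Morphometry of Cranial Suture Interdigitation
Version: 0.1.0
Authors@R:
    person("suturesim", "developers", email = "suturesim@example.org",
           role = c("aut", "cre"))
Description: Simulates the formation and maintenance of cranial and palatal
    sutures as a moving bone-mesenchyme interface driven by a diffusible
    osteogenesis-promoting factor, opposed by surface tension and fed by
    passive soft-tissue expansion. The osteogenic front moves at normal
    speed V = f(v) - sigma*kappa, realised as a forced Allen-Cahn phase
    field coupled to a semi-implicit screened-diffusion solve for the
    factor field. Includes morphometric measurements used on suture
    images (transect width, centerline-based maximum interdigitation
    amplitude, skeletonized suture length), synthetic image fixtures with
    closed-form ground truth, and parameter-screening sweeps that map
    suture width and interdigitation amplitude over the model parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
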