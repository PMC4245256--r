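Package: microsurv
Title: Microdosimetric Model Assembly for Targeted and Nontargeted Cell Survival
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts the clonogenic surviving fraction of irradiated cell
    populations from microdosimetric probability densities of specific energy
    at two spatial scales (the sub-nuclear domain and the cell nucleus).
    The targeted-effect channel implements a double stochastic microdosimetric
    kinetic (DSMK) survival model with a saturation correction for the
    high-LET overkill effect and an adaptive-response variant describing
    Bcl-2-mediated radioresistance. The nontargeted (bystander) channel models
    apoptotic-signal emission, propagation and reception in large cell
    populations for both broadbeam and microbeam irradiation geometries.
    Includes compound-Poisson construction of multi-event specific-energy
    distributions from single-event spectra, weighted least-squares parameter
    estimation with asymptotic covariance, iso-survival conversion of model
    survival into RBE-weighted photon doses, a synthetic-data generator with
    known ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
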