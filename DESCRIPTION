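Package: cztpet
Title: Simulation, Compton-Kinematics Event Processing and List-Mode OS-EM
    Reconstruction for a CZT Compton-Enhanced PET Prototype
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models a four-panel cadmium zinc telluride (CZT) coincidence
    detection system for Compton-enhanced positron emission tomography.
    Provides a Monte-Carlo photon transport engine for 511 keV annihilation
    photons in CZT (Klein-Nishina sampling with optional Doppler broadening,
    anode-pixel merging, Gaussian energy and position blurring), an analytic
    coincidence-response and sensitivity model with depth-of-interaction
    sublayers, construction of the near-field Compton response matrix over
    (deposited energy, scattering angle, inter-interaction distance),
    Compton-kinematics interaction sequencing and random-coincidence
    rejection with noise-equivalent-count-rate threshold optimization,
    maximum-likelihood geometry calibration, list-mode ordered-subset
    expectation-maximization image reconstruction, and the phantom
    generators and list-mode input/output needed to exercise the whole
    chain on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
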