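Package: polarcpm
Title: Multiscale Simulation of Cell Polarization and Motility
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the polarization and crawling of a single cell on a
    periodic hexagonal lattice. Rho-family GTPases (Cdc42, Rac, Rho) and
    phosphoinositides (PIP, PIP2, PIP3) evolve by reaction-diffusion with a
    tunable phosphoinositide feedback onto Cdc42/Rac activation,
    orientation-resolved actin filament and barbed-end fields drive
    protrusion, and a Cellular Potts shape engine couples pushing barbed
    ends and Rho-dependent contraction to stochastic edge dynamics.
    Includes stimulation protocols (graded, V-shaped and noisy stimuli,
    local injection, obstacles and walls), polarity and front-back
    interface metrics, and a force-velocity calibration of the shape
    engine against the polymerization-ratchet relation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
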