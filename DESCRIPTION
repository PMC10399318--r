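Package: fluidchain
Title: Bead-Chain Polymer Analogs in a Fluidized Bed
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Discrete-element simulation and analysis of macroscale bead-chain
    analogs of diffusive polymer chains agitated in an air-fluidized granular
    bed. Builds alternating resin-bead/crimp chain topologies with string
    anchors, integrates their dynamics under harmonic bond, angular, string,
    viscous damping and stochastic kick forces (Gaussian or Laplace), and fits
    stretched-exponential (exponential-power) velocity distributions to
    simulated or tracked tracer-bead velocities. Includes fluidized-bed design
    helpers (Ergun minimum fluidization velocity), hollow-bead density
    balancing, TrackMate-style track CSV input, synthetic track generation,
    and XYZ/LAMMPS-dump trajectory output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
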