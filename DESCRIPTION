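Package: cpmcompete
Title: Cellular Potts Simulation of Competitive Epithelial Invasion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-dimensional cellular Potts model of cell competition in
    epithelial monolayers. Cells are pixel sets on a lattice whose shapes
    evolve by Metropolis pixel-copy dynamics under an energy with area
    compressibility, perimeter contractility and cell-cell adhesion terms;
    stochastic division and death drive turnover. The package builds square
    tiled monolayers, runs single-type homeostatic-equilibrium protocols and
    three-stage two-type barrier-invasion protocols, and measures equilibrium
    densities, dead-cell fractions and invasion front speeds. A companion
    two-species reaction-diffusion model provides steady states, linear
    stability and closed-form pulled-front speeds, cross-validated by a 1D
    finite-difference solver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
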