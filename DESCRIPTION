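Package: colonyrot
Title: Active-Nematic Simulation and Trajectory Analysis of Rotating
    Epithelial Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models freely expanding epithelial cell colonies as a wet
    two-dimensional active nematic: Beris-Edwards Q-tensor dynamics coupled
    to a D2Q9 lattice-Boltzmann flow solver and an advected Cahn-Hilliard
    concentration field, on a periodic grid.  Alongside the simulator it
    provides the matching analysis pipeline for time-lapse cell-tracking
    data (radial and angular cell velocities about the cluster centroid,
    inner/outer region statistics, angular-velocity-versus-area trends)
    and for colony growth (exponential doubling-time fits, cell-density
    curves, confluence master curves, critical-area estimates), together
    with seeded synthetic-data generators so every stage is testable
    without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
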