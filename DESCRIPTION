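Package: microca
Title: Microdosimetry and Chromosome Aberrations for High-Energy Ion Beams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Monte Carlo simulation of energy deposition by high-energy ion
    beams in a spherical cell nucleus and of the chromosome aberrations that
    follow. A parametric track surrogate samples ion traversals of a periodic
    box, transports delta electrons, and splits the imparted energy into
    direct (nucleus-crossing tracks) and indirect (delta electrons of distant
    tracks) contributions. Downstream stages score nanometric dose in 20 nm
    voxels, lay out interphase chromatin as confined random walks, induce
    simple and complex double-strand breaks by Poisson sampling with a 500 eV
    complexity threshold, simulate 24 h of repair with distance-dependent
    misrepair, classify simple and complex exchanges, and fit linear-quadratic
    dose responses with bootstrap prediction intervals and dose-response
    comparison statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
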