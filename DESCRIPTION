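Package: pd2loop
Title: Coarse-Grained Protein Loop Modelling with a C-Alpha Statistical Potential
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Samples protein loop backbone conformations from a
    sequence-independent coarse-grained C-alpha potential energy function
    using local-move Monte Carlo simulated annealing, reconstructs backbone
    N/C/O atoms from the C-alpha trace by a geometric look-up method,
    filters conformations by Ramachandran quality with an adaptive
    acceptance rule, and regularises the result by conjugate-gradient
    minimisation in a united-atom backbone potential. Produces scored decoy
    ensembles with global-frame backbone RMSD statistics and bootstrap
    confidence intervals. Includes trainers for the 27-letter structural
    alphabet, the reference energies of the statistical potential, the
    hydrogen-bond tables, the Ramachandran map and the backbone look-up
    table, plus a synthetic-structure generator so the whole pipeline runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    yaml,
    stats,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
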