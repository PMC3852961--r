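Package: memorient
Title: Knowledge-Based Membrane Potential for Orienting Transmembrane Proteins
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Trains a depth-sliced knowledge-based statistical potential from
    pre-oriented transmembrane protein structures and uses it to position
    alpha-helical and beta-barrel membrane proteins in an implicit lipid
    bilayer. Rigid-body poses (rotation about x and y, translation along z)
    are optimised by a genetic algorithm, Hooke-Jeeves direct search, or
    exhaustive grid search. Includes hydrophobic membrane thickness
    estimation via a split head-group potential, orientation evaluation
    against reference structures (tilt angle, z-shift), decoy-discrimination
    statistics for model ensembles, and a synthetic structure generator for
    fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
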