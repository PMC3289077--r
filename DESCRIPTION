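Package: spabind
Title: Protein-RNA Interaction Site Prediction from Spatial Adjacent Residues
Version: 0.1.0
Authors@R: person("spabind", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts RNA-binding residues on protein chains from 3D
    complex structures. Labels interface residues by a heavy-atom distance
    cutoff, extracts spatial-adjacency feature encodings (profile windows,
    distance-weighted solvent accessibility, secondary-structure
    composition) alongside sequence-window baselines, and classifies with
    a hybrid SVM-KNN: an RBF-kernel support vector machine whose
    low-margin predictions are routed to a class-weighted k-nearest
    neighbour vote among the support vectors. Includes parsers for PDB,
    mmCIF, DSSP and PSI-BLAST PSSM files, a Shrake-Rupley accessible
    surface area fallback, a deterministic synthetic complex generator,
    a 5-fold cross-validation harness and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
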