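Package: dyesite
Title: Residue Scoring for Fluorophore Labeling and FRET Assay Design
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores every residue of a protein structure for its suitability
    as a covalent fluorophore labeling site using a naive-Bayes parameter
    score framework trained on a database of successfully labeled residues,
    and extends the score to the rational design of FRET assays.  Includes a
    per-residue parameter registry (conservation, solvent exposure, secondary
    structure, cysteine resemblance), a trained parameter-score model with
    counting-statistics uncertainties, label-score ranking, and three
    interdye-distance estimators: C-beta distances, a fast spherical-sector
    mean-position approximation, and a grid-based accessible-volume
    simulation with FRET-averaged distance conversion.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    pROC,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
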