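Package: prothull
Title: Hydrophobic Protrusions on Peripheral Membrane Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Convex-hull model of protein surface geometry for predicting
    interfacial membrane-binding sites of peripheral membrane proteins.
    Builds a coarse C-alpha/C-beta representation from PDB files, identifies
    vertex residues, hydrophobic protrusions, co-insertable protrusion pairs
    and the Likely Inserted Hydrophobe, computes side-chain solvent
    accessibility and membrane insertion coordinates, and provides
    family-weighted comparative statistics (weighted counts and fractions,
    log odds ratios with Wald confidence intervals) together with a
    permutation null model for co-insertion. Includes generators for
    synthetic structures and cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
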