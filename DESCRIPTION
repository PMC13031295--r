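Package: solvachrom
Title: Solvent-Aware 3D Neural Models for Chromophore Optical Properties
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting peak absorption wavelength, peak emission
    wavelength and photoluminescence quantum yield of chromophore-solvent
    pairs from 2D molecular graphs and 3D conformers. Implements a directed
    edge-message-passing (D-MPNN) solvent encoder, an SE(3)-invariant global
    attention backbone with a virtual molecule-level node and an equivariant
    coordinate-refinement head, solvent fusion by head concatenation or
    virtual-node injection, a joint masked property + Kabsch-aligned
    coordinate objective trained on multi-fidelity conformation pairs,
    Bemis-Murcko scaffold splitting and cross-validation, dataset curation
    utilities for SMILES/SDF/XYZ inputs, and a seeded synthetic
    chromophore-solvent data generator with a known solvatochromic ground
    truth for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
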