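Package: sift2d
Title: Two-Dimensional Structural Interaction Fingerprints for
    Protein-Ligand Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes two-dimensional structural interaction fingerprints
    (2D-SIFt): for every binding-site residue of a protein-ligand complex a
    7x9 count matrix records which ligand pharmacophore feature types
    (acceptor, donor, hydrophobe, negative, positive, aromatic, any-atom)
    engage in which interaction types (any, backbone, side chain, polar,
    hydrophobic, residue-acceptor, residue-donor, charged, aromatic).
    Pharmacophore features are perceived by SMARTS matching, interactions by
    explicit geometric criteria (distance cutoffs, hydrogen-bond angles,
    ring-stacking distance/angle rules, pi-cation distance). Matrices from
    collections of complexes can be aligned on generic residue numbers
    (GPCRdb style), averaged into silenced interaction profiles, screened
    for contact-frequency hotspots, contrasted as differential profiles,
    linearized to binary or count fingerprints with Tanimoto and Euclidean
    comparison, and rendered as heat maps. A synthetic-fixture generator
    produces toy complexes with analytically known descriptors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    ChemmineR,
    ChemmineOB,
    ggplot2,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
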