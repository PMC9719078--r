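Package: csalign
Title: Flexible Small-Molecule 3D Alignment and Alignment-Based Docking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully flexible compound-to-compound 3D structure alignment by
    global optimization of a hybrid shape-match/energy score with
    conformational space annealing (CSA), and alignment-based protein-ligand
    docking that adds a grid-based protein-ligand interaction energy.
    Includes a molecular data model with SDF/MOL2/PDB input, perception of
    rotatable torsions, rings and atomic charges, symmetry-aware heavy-atom
    RMSD, a ring-conformer library with Boltzmann sampling, and a
    programmatic fixture generator for benchmarking at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    bio3d,
    igraph,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
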