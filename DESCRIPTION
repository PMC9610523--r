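Package: dockpose
Title: Label-Invariant RMSD, Pose Clustering and Interaction Analysis for
    Molecular Docking Results
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the positional analysis of molecular docking results.
    Computes the root mean square deviation (RMSD) between docked ligand
    poses and a reference structure even when atoms are labelled in a
    different order, using a greedy depth-first graph-matching algorithm
    on the molecular graph, with an exhaustive isomorphism search as an
    exact oracle for small molecules.  Clusters pose sets on the pairwise
    RMSD matrix with the gromos, single-linkage and complete-linkage
    algorithms, extracts docking scores from AutoDock Vina and OpenEye
    output files, reports geometric receptor-ligand interactions
    (hydrogen bonds, ionic contacts, hydrophobic contacts, pi-stacking,
    metal coordination), and generates synthetic molecules and pose sets
    for testing.  Reads SDF, MOL, MOL2, PDB and PDBQT files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    methods,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
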