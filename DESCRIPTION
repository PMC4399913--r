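Package: gpcrnet
Title: Structure-Anchored Phylogenetics and Split Networks for
    Seven-Transmembrane Receptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for structure-based molecular evolution of
    rhodopsin-like G protein-coupled receptors: Ballesteros-Weinstein
    anchored composite alignments of the seven-transmembrane domain,
    uncorrected P and maximum-likelihood (JTT) distances, Neighbor-Joining
    and maximum-likelihood tree inference with NNI/SPR search and
    nonparametric bootstrap, NeighborNet circular split networks with
    non-negative least-squares split weights, iterative template-based
    trimming of large receptor repertoires, ligand- and sodium-site pocket
    profiling from coordinates, and voxel-grid consensus ligand volumes
    after 7TM superposition. Includes simulators for JTT sequence
    evolution and toy helix-bundle structures so every stage can be
    exercised without external databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    bio3d,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
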