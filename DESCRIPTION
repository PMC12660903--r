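Package: rnagate
Title: Geometric Descriptors, Path Coordinates, and Splicing Kinetics for
    Multidomain RNA Scaffold Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative structural analysis of dynamic multidomain RNA
    assemblies such as the group II intron domain 1 (D1) scaffold. Provides
    reading and writing of RNA coordinate files (PDB, mmCIF), rigid-body
    Kabsch superposition with iterative outlier rejection and per-residue
    displacement mapping, least-squares helical-axis fitting with
    inter-helical angle descriptors ('angles A-D'), gate-distance and
    radius-of-gyration measures, eta/theta pseudo-torsion analysis and
    bulged-in/bulged-out nucleotide classification, path-progress collective
    variables (spath/zpath) over milestone conformations, conformational
    ensemble quantification (pairwise RMSD matrices, descriptor series, tip
    displacements), and kinetic models for two-step ribozyme splicing and
    Michaelis-Menten spliced-exon reopening assays. A synthetic-structure
    generator produces idealized RNA duplexes, multi-helix constructs with
    prescribed descriptor values, morph paths, sub-state ensembles, and noisy
    kinetic time courses so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
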