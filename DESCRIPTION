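Package: abctraj
Title: Conformational, Membrane and Allosteric Network Analysis of ABC
    Transporter Trajectories
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trajectory-analysis toolkit for ATP-binding cassette (ABC)
    transporter molecular-dynamics ensembles. Computes the standard ABC
    conformational descriptors (intracellular/extracellular opening
    angles, nucleotide-binding domain distance and rocking-twist,
    Walker-A/signature distances, helix tilts, RMSD/RMSF, core PCA),
    Gaussian-mixture free-energy landscapes with core-state detection,
    pore-radius profiles at fixed bilayer depths, lipid order parameters,
    two-dimensional lipid densities, occupancy hotspots, membrane
    thickness and continuum deformation energetics, dynamic
    cross-correlation and community analysis, and mutual-information
    allosteric networks with current-flow communication efficiency and
    betweenness. Includes a synthetic pseudo-transporter, membrane and
    ligand generator producing ensembles with known ground-truth
    descriptor values, correlation structure and lipid order, so that
    every analysis stage is testable without running molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
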