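Package: xlwalk
Title: Crosslink-Restrained Coarse-Grained Integrative Modeling of
    Receptor-Tethered Flexible Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrative structural modeling of a flexible protein tethered
    to a rigid multi-subunit receptor, driven by crosslinking mass
    spectrometry (XL-MS) distance restraints.  Parses and filters crosslink
    identification tables (q-value and PSM-count thresholds), builds hybrid
    rigid-body/flexible-bead representations from PDB coordinates, scores
    models against flat-bottom crosslink, excluded-volume and sequence
    connectivity restraints, samples good-scoring configurations by seeded
    Monte Carlo annealing, clusters the resulting ensembles and builds
    MRC-writable localization probability densities.  Also provides the
    structural-state comparison toolbox used for helical filament
    assemblies: Kabsch superposition, center-of-mass shifts, screw/helical
    parameters (twist, rise, pitch), Shrake-Rupley solvent-accessible
    surface areas and buried interface areas, and lattice-register
    displacements.  A synthetic-data generator produces toy receptor/ligand
    systems with a known ground-truth path and simulated crosslink tables
    so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
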