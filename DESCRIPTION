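Package: connexon
Title: Protomer Conformation Ensembles and Ion Permeation Statistics for
    Gap-Junction Channels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying conformational heterogeneity of oligomeric
    membrane channels from symmetry-expanded single-particle classification
    metadata, and for measuring ion permeation from molecular-dynamics-style
    trajectories. Reads and writes RELION-3.1 STAR particle tables, performs
    C6/D6 symmetry-expansion bookkeeping, maps 3D-class labels to protomer
    conformational states, and summarises per-channel state compositions.
    Provides binomial random-placement null models, necklace (cyclic
    ring-arrangement) statistics, goodness-of-fit and neighbour-coupling tests
    for hexameric rings. Computes crossing-count ionic currents, single-channel
    conductance with water-model viscosity correction, ion selectivity, axial
    concentration profiles and 3D density-flux maps from ion trajectories, and
    HOLE-style inscribed-sphere pore-radius profiles from atomic models.
    Includes seeded synthetic-data generators (classification metadata with
    tunable state fraction and ring coupling, drift-diffusion ion trajectories
    with a closed-form current oracle, toy pore structures) with exact
    reference distributions for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
biocViews: CryoEM, StructuralPrediction, Software
RoxygenNote: 7.3.3
Collate: 
    'connexon-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'conformation.R'
    'permeation.R'
    'pore.R'
    'simulate.R'
    'star-io.R'
    'symmetry.R'
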