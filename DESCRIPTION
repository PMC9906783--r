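Package: irphos
Title: Machine Learning Prediction of Iridium Phosphor Excited-State Properties
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for data-driven design of bis-cyclometalated iridium(III)
    phosphors of the form [Ir(CN)2(NN)]+. Provides molecular-graph
    featurization (revised autocorrelations, Coulomb-decay autocorrelations),
    circular-fingerprint similarity features, ligand electronic descriptor
    handling, a seeded synthetic-data generator emulating a combinatorial
    experimental phosphor library, neural-network / random-forest / ridge
    regression with random and ligand-grouped splits, latent-space distance
    uncertainty quantification with gated screening of hypothetical
    complexes, and post-processing of spin-orbit TDDFT triplet-sublevel
    output into Boltzmann-averaged radiative lifetimes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    nnet,
    randomForest,
    MASS,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
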