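Package: cemfwd
Title: Complete Electrode Model Forward and Inverse Simulation for EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-element forward simulation of electroencephalography (EEG)
    on tetrahedral head meshes with the complete electrode model (CEM) and the
    point electrode model (PEM), Whitney (Raviart-Thomas) synthetic dipole
    sources, lead-field construction via direct, Schur-complement and
    transfer-matrix routes, minimum current estimation by the iterative
    alternating sequential (IAS) algorithm, and the RDM/MAG/PD/AD/ND
    comparison measures. Includes a synthetic layered-sphere neonatal head
    generator with skull fontanel openings and a 74-electrode cap, plus
    scripted desk-scale reproductions of CEM-vs-PEM and open-vs-closed-skull
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    generics,
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
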