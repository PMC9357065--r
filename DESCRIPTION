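Package: plgictools
Title: Conformational Metrics and Funnel Metadynamics for Pentameric
    Ligand-Gated Ion Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative structural analysis of pentameric ligand-gated ion
    channel (pLGIC) models: extracellular/transmembrane domain (ECD-TMD)
    twist dihedrals, normalized ECD spread ("blooming"), Cartesian principal
    component analysis of Calpha ensembles, sphere-fitting pore-radius
    profiles, and ligand-residue contact frequencies.  Also provides a
    desk-scale two-dimensional well-tempered funnel metadynamics engine:
    funnel restraint geometry built from binding-site residues, overdamped
    Langevin sampling of collective-variable space on analytic model
    potentials, recrossing-based convergence diagnosis, and free-energy
    surface estimation by final-bias scaling and by time-dependent
    reweighting.  Synthetic-data generators (pseudo-pentamers with imposed
    twist/bloom, double-well potentials, toy pore linings, contact
    ensembles) make every analysis stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
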