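Package: nanocorona
Title: Coarse-Grained Prediction of Biomolecular Corona Formation on Nanoparticles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Multiscale coarse-grained pipeline for predicting the
    biomolecular corona that forms on metallic nanoparticle surfaces.
    Biomolecules are represented as rigid one-bead-per-residue models
    interacting with a spherical nanoparticle through tabulated short-range
    potentials of mean force, a screened-Coulomb electrostatic term and an
    optional Hamaker core term. Orientation-resolved adsorption energies are
    Boltzmann-averaged into heatmaps, converted to adsorption and desorption
    rate constants by kinetic collision theory and detailed balance, and fed
    into an event-driven kinetic Monte Carlo simulator of competitive
    adsorption of hard-sphere adsorbates, with optional displacement of
    weaker binders and quasi-equilibrium rate scaling for fast species.
    Includes generators for synthetic potentials, toy molecules and a
    bundled milk-on-aluminium reference system.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
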