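Package: azeopatch
Title: Inverse Thermodynamic Design of Azeotropes in Patchy-Particle Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for programming the phase behavior of multicomponent
    patchy-particle (Kern-Frenkel) mixtures. Mixtures are specified as
    species/patch interaction graphs with energy-weighted bonding edges.
    Phase behavior is predicted with Wertheim first-order thermodynamic
    perturbation theory (mass-action bonding probabilities, free energy,
    equation of state, two-branch Gibbs free-energy curves, common-tangent
    coexistence and azeotrope location), and azeotropic points are relocated
    to prescribed compositions by iterative tuning of bond energies.
    Predictions can be validated with the built-in Monte Carlo engine
    (NVT, NPT, Gibbs-ensemble and grand-canonical sampling with
    aggregation-volume-bias moves) and with the S0 structure-factor route
    to chemical potentials (Ornstein-Zernike extrapolation of partial
    structure factors and Kirkwood-Buff integration over composition).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
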