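Package: entroflux
Title: Maximum-Entropy-Production Prediction of Metabolic Flux Structure
    from Elementary Flux Modes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enumerates elementary flux modes (EFMs) of small metabolic
    reaction networks, computes condition-adjusted reaction thermodynamics
    (pseudoisomer averaging, extended Debye-Hueckel ionic-strength and pH
    corrections, gas/liquid phase averaging) for each mode, and predicts
    mode usage probabilities from a Boltzmann-type distribution obtained by
    maximizing the rate of entropy production of a chemostat-like culture at
    steady state. From the fitted distribution the package predicts the
    overall growth stoichiometry, external and internal reaction rates, the
    maximum specific growth rate and minimum doubling time, and system-level
    entropy and Gibbs energy balances, and compares predicted with measured
    fluxes. Includes seeded synthetic-data generators for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
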