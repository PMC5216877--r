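Package: deerquant
Title: Quantifying ABC Transporter Conformational Equilibria from DEER Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of pulsed double electron-electron
    resonance (DEER) dipolar evolution data for quantifying conformational
    equilibria of membrane transporters. Provides a Fresnel-integral dipolar
    kernel forward model, stretched-exponential background correction,
    non-negative Tikhonov regularization with L-curve selection of the
    regularization parameter, a constrained two-Gaussian procedure for
    extracting inward-facing versus outward-facing population fractions and
    ranking nucleotide conditions, and ATPase kinetics utilities
    (Michaelis-Menten and hyperbolic-inhibition fits, Cheng-Prusoff
    inhibition constants with propagated standard errors, turnover
    bookkeeping). Includes deterministic synthetic-data generators so the
    whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    pracma,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
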