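Package: microvisc
Title: Microscale Rheometry of Polymer Solutions from Microchannel Velocity Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the shear-rate-dependent viscosity of a polymer solution
    (such as a liquid polyethylene-glycol hydrogel precursor) from velocimetry
    profiles measured across a microchannel. Measured midplane profiles are
    fitted to a cosh-family experimental curve with wall slip, normalized by
    their average velocity, and fitted to the power-law duct profile to obtain
    a per-case power-law index; differential viscometry integrates the index
    over shear rate to recover the viscosity curve, and a log-log fit yields
    the consistency index K and overall power-law index n. A finite-difference
    Picard solver for steady power-law flow with wall slip in rectangular
    ducts, with the Newtonian series solution as an oracle, provides the
    forward model, and a synthetic micro-PIV profile generator makes the
    whole pipeline testable without raw experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
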