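Package: liflux
Title: Lithium Isotope Fractionation by Cellular Ion Transport
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic simulation and calibration of stable lithium isotope
    (6Li/7Li) fractionation by cellular ion transport. Couples passive
    electrodiffusive channel fluxes (Goldman-Hodgkin-Katz electrodiffusion
    with a dynamic membrane potential) to an electroneutral dimeric Na+/H+
    exchanger (NHE) modelled as a master equation over protomer occupancy
    states with first-come-first-served translocation, kinetic isotope
    effects, sodium competition and Monod-Wyman-Changeux proton allostery.
    Provides whole-cell uptake simulations (time courses, dose responses,
    pH and sodium scans), delta-7Li bookkeeping against the LSVEC standard,
    Michaelis-Menten, MWC and joint ODE parameter fitting by
    Levenberg-Marquardt, a staged calibration of the default parameter
    bundle, and seeded generators of synthetic measurement tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
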