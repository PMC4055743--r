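Package: sfkin
Title: Pre-Steady-State Kinetic Analysis of Stopped-Flow Fluorescence Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mass-action kinetic modelling of DNA-repair enzyme mechanisms
    observed by stopped-flow fluorescence. Provides declarative kinetic
    schemes (sequential enzyme-substrate binding equilibria, an irreversible
    catalytic step and a product-release equilibrium), stiff ODE integration
    of species time courses, linear fluorescence observation models including
    the dual-band ratiometric statistic of ESIPT probes, a synthetic
    stopped-flow trace generator with instrument dead time and replicate
    averaging, and global multi-start nonlinear least-squares estimation of
    rate constants across concentration series with AIC/F-test model
    comparison. Ships the published rate constants for Endonuclease VIII
    (Nei) processing 5,6-dihydrouracil substrates reported by different
    fluorescent probes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
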