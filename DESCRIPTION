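Package: stoopsim
Title: Physics-Based Simulation of Falcon Attacks on Maneuvering Prey
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A physics-based aerial predator-prey simulator for studying
    attacks by peregrine falcons on erratically maneuvering prey. Implements a
    quasi-steady, wingbeat-averaged blade-element flight performance model
    driven by species morphology (wingbeat frequency, wingspan, masses, wing
    area, aspect ratio, body drag coefficient), pursuit by pure proportional
    navigation with delayed and noisy vision, erratic (jinking) evasion with
    bang-bang roll control, genetic-algorithm tuning of guidance parameters,
    Monte Carlo catch-success experiments over attack geometries, and smooth
    logistic response-surface analysis of the results.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    mgcv,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
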