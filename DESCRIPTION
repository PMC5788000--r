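Package: orchardsim
Title: Source-Sink Simulation of Peach Tree Growth and Fruit Quality Under Water Stress
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A per-fruiting-unit simulator of peach tree carbon and water
    relations over a growing season. Couples canopy radiation interception on
    ellipsoidal fruiting-unit envelopes, a sunlit/shaded leaf energy balance
    with Jarvis stomatal conductance, steady-state water transfer through the
    tree hydraulic architecture, water-limited light-saturated photosynthesis,
    degree-day driven potential organ growth with a leaf-water-potential
    reduction function, distance-decay carbon allocation with root-shoot
    balance and reserves, and a biophysical fruit growth model (turgor-driven
    expansion plus a four-pool sugar metabolism system). Includes a synthetic
    forcing generator for deficit-irrigation treatments, a 13-scenario virtual
    experiment separating source (photosynthesis) from sink (growth)
    limitation, and calibration utilities (relative RMSE, weighted global
    criterion, quantile-envelope potential-growth fits, Nelder-Mead fits of
    the stress thresholds and sugar parameters).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
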