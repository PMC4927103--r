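Package: drainfieldN
Title: Nitrogen Fate and Transport in Onsite Wastewater Soil Treatment Areas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates variably saturated water flow (Richards equation with
    van Genuchten-Mualem hydraulics) and reactive nitrogen transport
    (advection-dispersion with a sequential NH4 -> NO3 -> N2 decay chain and
    water-content, temperature and carbon-depth dependent Michaelis-Menten
    nitrification/denitrification kinetics) in two-dimensional drainfield
    mesocosms of onsite wastewater treatment systems. Includes pressurized
    shallow narrow, Geomat and pipe-and-stone drainfield geometries, pulsed
    effluent dosing with seepage-face outflow, Gauss-Newton inverse
    calibration with composite scaled sensitivities, nitrogen mass-balance
    accounting, synthetic observation generation, and climate-change
    scenario analysis (warmer soil, raised water table).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
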