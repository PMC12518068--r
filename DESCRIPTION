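Package: dietopt
Title: Diet Optimization by Lexicographic Goal Programming
Version: 0.1.0
Authors@R: person("Diet", "Modeler", email = "dietopt@example.org",
    role = c("aut", "cre"))
Description: Tools for designing nutritionally adequate, low-emission diets
    from observed food-consumption data. Implements a lexicographic linear
    goal program that reallocates food-item quantities within and/or between
    food groups to minimize deviation from nutrient guidelines, greenhouse
    gas emissions and dietary change; a loss-adjusted carbon-footprint
    calculation for composite foods decomposed into primary commodities;
    consumer-acceptability metrics (total dietary change, removed-item
    fraction, within-group share concentration); and a synthetic food-system
    generator so the whole pipeline is testable without survey downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    boot,
    optparse,
    withr
Config/testthat/edition: 3
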