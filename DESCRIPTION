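Package: no2home
Title: Residential NO2 Exposure from Gas Stoves and Outdoor Infiltration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models total residential nitrogen dioxide (NO2) exposure by
    combining indoor emissions from gas and propane stoves with infiltration
    of outdoor NO2. Provides a simplified multizone well-mixed mass-balance
    simulator with dummy tracers for infiltration and air exchange, a weighted
    factorial scenario engine over occupant behaviour and environment, chronic
    and acute (maximum hour-averaged) exposure statistics, population-weighted
    aggregation of exposure from ZIP-code to county and national level against
    WHO and EPA benchmarks, and Monte Carlo uncertainty multipliers. A
    synthetic-data module generates housing stock, floorplans, behavioural
    distributions and outdoor concentrations so the full pipeline runs
    self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
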