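Package: foodscape
Title: Neighborhood Food Deserts, Food Swamps and Socioeconomic Inequality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ecological analysis of community food environments around
    schools. Aggregates census-tract socioeconomic data to neighborhoods, computes
    three inequality measures (per-capita income terciles, a Getis-Ord Gi*
    segregation index over first-order rook contiguity weights, and a composite
    deprivation index), classifies food establishments by economic-activity code
    into the CAISAN in natura / ultraprocessed / mixed taxonomy, flags neighborhoods
    as food deserts (healthy-establishment density below a percentile threshold) and
    food swamps (unhealthy-establishment count above a fixed threshold), and produces
    stratified prevalence cross-tabulations with Pearson chi-square tests. Includes a
    seeded synthetic-city generator (lattice neighborhoods, tract microdata,
    establishment registry, school roster) so the full pipeline can be exercised and
    validated without restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
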