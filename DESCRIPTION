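Package: geoprev
Title: Multi-Scale Spatial Analysis of Disease Period Prevalence
Version: 0.1.0
Authors@R:
    person("geoprev", "developers", email = "geoprev@example.org",
           role = c("aut", "cre"))
Description: Tools for multi-scale geographic analysis of disease period
    prevalence over nested polygon geographies: sex-interaction point-pattern
    tests (Ripley's K, Cross-L, Difference-K with random-labeling envelopes and
    the Diggle-Cressie-Loosmore-Ford test), period-prevalence aggregation,
    global, local and bivariate Moran's I with permutation inference, the
    geographical-detector q-statistic for stratified spatial heterogeneity, and
    a random-Voronoi-zonation experiment probing the modifiable areal unit
    problem.  Includes a synthetic-geography generator (Voronoi districts nested
    in zones, log-normal populations, population-proportional or clustered case
    point patterns) so the full pipeline is testable without confidential
    health records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
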