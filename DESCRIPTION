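Package: wheatstress
Title: Simulating Wheat Yield Losses from Extreme Drought and Heat Around
    Flowering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for estimating wheat yield losses caused
    by short-term extreme drought and extreme heat around flowering, under
    baseline and delta-change future climates.  Includes a stochastic daily
    weather generator (first-order Markov precipitation occurrence, gamma
    wet-day amounts, autocorrelated Gaussian temperatures), a simplified
    process-based wheat season model (thermal-time phenology, radiation-use
    efficiency growth with CO2 response, Priestley-Taylor soil water
    balance, empirical canopy temperature), piecewise flowering-window
    stress response functions acting on grain number and grain weight, the
    paired tolerant/sensitive simulation protocol yielding drought and heat
    stress indices (DSI, HSI) with 95th-percentile one-in-twenty-year
    summaries, and multi-site country-level aggregation with extreme-site
    selection.  A synthetic-data module generates contrasting site
    climates, soils, cultivars and GCM-like delta ensembles so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
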