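Package: pilotwhaleDEB
Title: Dynamic Energy Budget Life-History Simulation for Long-Finned Pilot Whales
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An individual-based bio-energetic (Dynamic Energy Budget) model of
    a female long-finned pilot whale (Globicephala melas) and her calves, with
    seasonally varying resources and yearly recurrent foraging-disturbance
    windows. Simulates complete female life histories from weaning to death with
    an event-driven ODE integrator (compiled core), tracks reserve mass, body
    condition, reproduction and starvation-dependent survival, and estimates
    lifetime reproductive output (R0), vital-rate statistics with bootstrap
    confidence intervals, and the disturbance duration at which R0 falls below
    replacement. Intended for exploring population consequences of disturbance
    (PCoD) in income-breeding marine mammals.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
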