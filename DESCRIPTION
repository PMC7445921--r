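Package: drugflow
Title: Stock-and-Flow Simulation of Essential-Medicine Supply Chains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Deterministic stock-and-flow simulation of a national essential-medicine
    supply chain with manufacturers, procurers, warehouses and health facilities.
    Shipments are Gaussian flow pulses (or their discrete limit) delayed by transport
    times; patient demand drains facility stock continuously. The package simulates
    open-loop shipment schedules and a digital-tracking forecasting controller that
    sizes each shipment to hold stocks at desired levels, applies health-system
    intervention scenarios (prevention, roads, workforce, vehicles) as parameter
    transforms, and reports stockout and stock-holding metrics for scenario comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
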