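Package: tradewind
Title: Spatiotemporal Tradeoff Analysis for Siting Offshore Wind Energy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision support for siting offshore wind energy development
    (OWED) where wildlife impacts differ in space and time. Computes per-cell
    net present value of a fixed-configuration wind farm from a Weibull wind
    resource and cable distance, a cumulative seabird sensitivity surface from
    species densities weighted by collision/displacement vulnerability, and
    monthly cetacean sensitivity surfaces weighted by NatureServe conservation
    status. A utility-function simulation over a grid of weightings ranks
    candidate sites in space, and per-site monthly cetacean profiles recommend
    the least-impacting month for acoustically harmful pre-operational
    activities such as pile driving. Includes a synthetic scenario generator
    with planted ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    yaml,
    fitdistrplus
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
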