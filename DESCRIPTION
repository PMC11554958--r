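Package: beescape
Title: Restoration Scenarios for Wild-Bee Pollination in Agricultural Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing how much restoring marginal agricultural
    lands (abandoned fields, degraded fields and field-edge flower strips)
    can enhance wild-bee pollination provision and natural-habitat coverage.
    Implements detection of abandoned fields from cultivation histories and
    of degraded fields from pixel-wise NDVI trends, a Lonsdorf-style
    foraging-kernel model of relative wild-bee abundance, dependency-weighted
    pollination demand, tertile bivariate supply-demand classification with
    demand hotspots, focal natural-cover statistics, five restoration
    scenarios with vector-accounted area ledgers, and supply-to-demand ratio
    aggregation on a 1-km grid. A synthetic-landscape generator with known
    ground truth makes the full pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
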