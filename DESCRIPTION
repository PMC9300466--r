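Package: phanerodiv
Title: Spatially Explicit Diversification Modelling of Phanerozoic Marine Diversity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates environment-dependent logistic and exponential
    diversification of marine invertebrate genera on drifting seafloor
    habitats over Phanerozoic time scales. Provides a synthetic
    paleogeography generator (Lagrangian seafloor points with flooding,
    drift, ridge birth and subduction), mass-extinction forcing with
    imputed negative net diversification rates, transect-based
    integration of regional diversity maps into global diversity curves
    using distance decay of taxonomic similarity, carrying-capacity
    calibration against reference diversity curves via Lin's concordance
    correlation coefficient, and saturation diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
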