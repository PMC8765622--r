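Package: cocoazone
Title: Edaphoclimatic Suitability and Climate-Adaptation Zoning for Cocoa
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ensemble habitat-suitability modelling and climate-adaptation land
    zoning for a perennial crop (cocoa, Theobroma cacao) in an Amazon-like
    landscape. Builds surface-range-envelope pseudo-absences, fits a small
    registry of presence/pseudo-absence learners gated by the True Skill
    Statistic, averages general-circulation-model scenarios into a consensus
    climate, applies soil-by-infrastructure suitability rules, and discretises
    current and future suitability into intensification, expansion,
    diversification, conversion and not-recommended zones with km2 area
    accounting, derived change statistics and a territory-by-scenario analysis
    of variance. A fully synthetic world generator with known true suitability
    makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    mgcv,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
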