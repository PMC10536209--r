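Package: cacgdd
Title: Olive Phenology from Chill, Anti-Chill and Growing Degree Days
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts the sprouting, blooming and pit-hardening dates of olive
    cultivars from daily minimum/maximum temperature series. Sprouting comes
    from a sequential chill and anti-chill days model built on the single
    triangle degree-day method; blooming and pit hardening are then forced
    with clamped growing degree days accumulated from the sprouting date.
    Includes bounded genetic-algorithm calibration against phenological
    observations, leave-one-out cross-validation, Taylor-diagram statistics,
    a seeded Mediterranean synthetic weather and observation generator, and
    cell-by-cell projection of phenological dates over regular
    latitude-longitude temperature climatologies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
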