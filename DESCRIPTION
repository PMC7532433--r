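Package: phenochill
Title: Chilling and Forcing Models for Spring Phenology Under Climate Warming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for measuring winter chilling accumulation (CA) and spring
    heat requirement (HR) of temperate perennials from daily temperature
    series. Implements twelve daily rate-of-chilling models (threshold,
    Utah-type, dynamic chill-portion, Weibull and triangular forms) and eight
    rate-of-forcing models (growing-degree-day, daytime-weighted, logistic and
    growing-degree-hour forms) as a uniform registry; accumulates them over
    dormancy-season calendar windows; tests each chilling model against the
    physiological expectation of a negative CA-HR relationship; fits the
    empirical CA-HR rule and simulates budburst dates under historical and
    scenario climates; and generates synthetic Central-European station
    climates and mechanism-driven phenology records so the whole chain is
    testable without external archives.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
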