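Package: tendonload
Title: Cumulative Achilles Tendon Load Monitoring from Plantar Force Insoles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating and summarizing real-world Achilles tendon
    load from three-channel plantar force insole recordings. Converts heel,
    midfoot and forefoot forces into a body-weight-normalized tendon load
    series via an ankle moment balance, accumulates thresholded loading time
    and impulse (overall >= 0.3xBW and high-level >= 3.0xBW), normalizes
    cumulative loads per loading hour, quantifies how many monitoring days are
    needed through day-level subsampling (mean absolute percent error and
    correlation against the full dataset), and correlates loading metrics with
    clinical plantar-flexor function measures. Includes quality control for
    baseline drift and erroneous sessions, a wear-protocol adherence check,
    and a seeded synthetic cohort generator with analytic ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
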