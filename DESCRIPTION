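Package: nemalife
Title: Cohort Life Tables and Life-History-Trait Demography for Nematodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds age-specific survival/fecundity life tables from
    per-individual, interval-censored cohort observations of nematodes
    cultured with the hanging drop method, and computes the classical
    life-history-trait metrics: net reproductive rate R0, total fertility
    rate, the intrinsic rate of natural increase from the Euler-Lotka
    equation, population doubling time, three generation-time measures,
    and a snapshot hatching-time estimator. Includes an individual-based
    simulator of a synchronized selfing-hermaphrodite cohort with an
    interval-censoring observer, a Leslie-matrix growth-rate oracle, and
    tab-separated readers/writers for cohort logs and life tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
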