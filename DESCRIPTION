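Package: zerodose
Title: Identifying Positive Outliers in Reducing Zero-Dose Children
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing geographic equity in routine childhood
    immunization. Converts subnational DTP1 coverage panels into zero-dose
    (no-DTP) prevalence, computes national levels and 5th-95th percentile
    subnational gaps by country-year, quantifies absolute and relative change
    over a study window, ranks countries on both dimensions to identify
    exemplar countries ("positive outliers"), and pairs target countries with
    baseline-matched neighbours to contrast divergent trajectories. Includes
    a seeded synthetic panel generator that emulates the statistical structure
    of modelled subnational coverage estimates, so the full pipeline is
    testable without access to the original estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
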