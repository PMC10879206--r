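Package: precpath
Title: Construction and Optimization of Multi-Platform Precision Diagnostic Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds sequential diagnostic pathways across multiple assay
    platforms. Each patient is routed through an ordered sequence of platforms
    and receives a final class as soon as an ensemble confidence score, derived
    from repeated cross-validation votes of diagonal linear discriminant
    models, clears a threshold; the final platform forces a decision.
    Candidate platform orderings are compared on balanced accuracy and
    cumulative assay cost by weighted rank aggregation. Includes a frozen
    ensemble transfer mode using pairwise log-ratio features with
    patient-level standardization for application to external cohorts on
    different measurement scales, a seeded synthetic multi-platform cohort
    generator, figure-backing data builders, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
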