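Package: pecnmr
Title: Property-Energy Consistent Basis-Set Contraction and NMR Shift
    Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for NMR-oriented Gaussian basis sets: a data model and
    parsers for segmented-contracted basis sets, structural operations
    (uncontraction, releasing a p-function), the property-energy consistent
    (PEC) Monte-Carlo optimizer of contraction coefficients against target
    isotropic shieldings under a total-energy constraint, mean absolute
    (percentage) contraction error metrics, and a linear-scaling benchmark
    protocol mapping computed shieldings onto experimental chemical shifts
    via per-nucleus regression scored with corrected mean absolute errors.
    Shielding and energy evaluations go through a pluggable backend contract
    with a deterministic analytic surrogate for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
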