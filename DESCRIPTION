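Package: druggrade
Title: Growth-Rate-Adjusted Death (GRADE) Scoring of Drug Dose Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrated analysis of drug-induced growth inhibition and cell
    death from live/dead cell-count time courses. Computes relative viability
    (RV), fractional viability (FV) and growth-rate inhibition (GR) metrics
    from dose-response imaging data, fits four-parameter logistic
    dose-response curves, exponential growth curves and lethal-fraction death
    kinetics, simulates the theoretical (GR, FV) response space under an
    exponential birth-death model, inverts observed (GR, FV) pairs to average
    proliferation and death rates, and scores the fraction of an observed
    drug response attributable to cell death on a 0-100 GRADE scale. Includes
    a synthetic-data generator for noisy count time courses with known
    ground-truth rates.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
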