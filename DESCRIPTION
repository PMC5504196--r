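Package: trirace
Title: Trimodal Race Model Inequalities for Redundant-Signals Reaction Times
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the redundant signals effect in trimodal
    (audio-visual-somatosensory) reaction time experiments. Computes the full
    family of bimodal and trimodal race model inequality bounds on the
    redundant-condition distribution function (Boole, Bonferroni-type, their
    sharp pointwise minimum, and restricted bounds for incomplete designs),
    quantifies where and by how much an observed distribution violates them,
    and simulates race and superposition (coactivation) architectures with
    Erlang channel latencies and controlled trivariate dependence via a
    calibrated Gaussian copula. Includes correlation-admissibility checks
    (Stanley-Wang range), context-invariance diagnostics, fixture generators,
    and a small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    optparse,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
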