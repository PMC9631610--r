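Package: gcsde
Title: Stochastic Modelling of Genomic GC-Content Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the evolution of genomic GC content in asexually
    reproducing, non-recombining organisms as a linear stochastic
    differential equation whose AT-to-GC and GC-to-AT mutation rates are
    perturbed by Gaussian white noise scaled by a deterministic schedule
    c(t). Provides closed-form solutions (deterministic trajectory,
    expectation, and Ito-isometry variance), seeded Euler-Maruyama and
    exact path simulators, a Girsanov change of measure with
    Radon-Nikodym weights and a driftlessness validation, a stochastic
    Luria-Delbruck mutation model built on geometric Brownian population
    growth, nonlinear least-squares estimation of the mutation-rate
    constants from SNP GC-content observations, and utilities for GC
    content and Chargaff parity of nucleotide sequences. Includes a
    command-line interface for reproducible simulation runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    optparse,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    tibble,
    utils
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
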