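Package: transloss
Title: Mutation and Selection Dynamics of Transgene Loss in Serial
    Transfer Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the evolutionary stability of engineered microbial
    genomes propagated by serial transfer. Provides joint maximum-likelihood
    estimation of the per-replication transgene loss rate (mu) and the
    selection coefficient against carriers (s) from binomial genotyping
    counts, closed-form transgene frequency dynamics with evolutionary
    half-life (t50) prediction and re-engineering gain surfaces, a
    tau-leaping stochastic simulator of serial passage experiments with
    bottleneck transfers, a per-transfer (discrete-time) estimator for
    protocols without a known within-culture growth rate, and a
    parameter-recovery validation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
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
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
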