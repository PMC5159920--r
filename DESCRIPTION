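Package: ultrahill
Title: Discovering Ultrasensitive Dose-Response Genes from Replicated
    Expression Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering genes with ultrasensitive
    (switch-like) dose-response functions from a multi-dose, replicated
    FPKM expression matrix: staged filtering (non-zero expression,
    1-FPKM detectability, Kruskal-Wallis dose response, replicate
    correlation), max-normalisation and dose-response shape
    classification (monotone increase/decrease, stripe, antistripe),
    Bayesian Hill-function fitting by Metropolis-Hastings MCMC with
    binned posterior modes of the apparent Hill coefficient, candidate
    selection by fold change and basal expression, and per-chromosome
    summaries. Includes a synthetic-cohort generator with full ground
    truth so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
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
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
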