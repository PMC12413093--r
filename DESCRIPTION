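Package: lowrankOU
Title: Stationary Stochastic Activity in Low-Rank Linear Recurrent Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analytic and simulation tools for linear recurrent neural
    networks with low-rank connectivity driven by white stochastic inputs
    (multivariate Ornstein-Uhlenbeck processes). Constructs rank-R
    connectivity from prescribed vector overlaps, computes the stationary
    activity covariance, its eigen-structure and participation-ratio
    dimensionality in closed form, and validates the theory against direct
    Euler-Maruyama simulation. Includes the two-unit excitatory-inhibitory
    circuit and its non-normal amplification analysis, and tidy sweep
    drivers reproducing the figure-level computations as tables.
License: MIT + file LICENSE
Encoding: UTF-8
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
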