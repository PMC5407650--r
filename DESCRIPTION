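Package: burstbif
Title: Burst-Noise Driven Stochastic Bifurcations in the Schlogl Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for studying how bursty molecule production reshapes
    the stationary behaviour of the Schlogl autocatalytic reaction scheme
    without altering its deterministic rate equation. Provides the
    deterministic fixed-point and cusp (discriminant) analysis, analytical
    Fokker-Planck stationary densities with extrema location, exact
    stationary solutions of the truncated chemical master equation, an
    exact Gillespie stochastic simulator for burst reactions, and
    phenomenological-bifurcation scans over rate parameters and burst
    size, including the analytic noise-induced shift of stationary modes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
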