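Package: plastmix
Title: Synaptic Plasticity Outcome Classification and Input-Mixing Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of pairing-induced synaptic plasticity in cortical
    slice recordings. Provides sweep-level quality control (access
    resistance, membrane potential and baseline-stability exclusions), a
    two-criterion classifier of long-term potentiation, depression or no
    change from pre- and post-pairing response amplitudes, and a Monte
    Carlo input-mixing simulation that assembles simulated compound
    responses from a database of unitary connections under a segregation
    parameter, together with the supporting statistics (variance F-test,
    two-sample Kolmogorov-Smirnov, Shapiro-Wilk, Gaussian kernel density
    estimation, empirical CDFs). A synthetic-data generator emulates the
    standard pairing protocol so the full pipeline is reproducible without
    raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
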