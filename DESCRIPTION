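Package: eldercap
Title: Multi-Objective Capacity Planning for Graded Elder-Care Institutions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cycle-by-cycle construction planning for five grades of
    elder-care institutions as a bi-objective integer program: maximise
    economic benefit while minimising social cost, subject to beds-per-1000
    floors and per-grade bed-share constraints. Problems are solved with an
    elitist non-dominated-sorting genetic algorithm over integer-coded plans,
    a single plan is selected from the Pareto archive by TOPSIS, and a
    "smart community" scenario variant (halved income coefficients from a
    switch cycle, escalating per-cycle bed-rate targets) is supported.
    Ships the Nanjing parameterisation as a built-in fixture, a synthetic
    problem generator, and a brute-force Pareto oracle for small instances.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
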