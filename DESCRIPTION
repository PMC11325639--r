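Package: wormkin
Title: Kinetic Prediction of Pesticide Accumulation in Earthworms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: One-compartment toxicokinetic modelling of pesticide uptake and
    elimination in earthworms. Regression models predict uptake and
    elimination rate constants from chemical hydrophobicity (log Kow / log Dow,
    log Kom, TPSA), soil organic matter, and earthworm surface-area and lipid
    traits; a first-order kinetic model with exponentially decaying exposure
    turns those constants into time-resolved body residues and steady-state
    bioconcentration factors. Includes soil-porewater partitioning (Kd / Kom),
    applicability-domain checking, OECD-317-style kinetic fitting, stepwise
    multiple linear regression with collinearity screening, leave-one-out
    cross-validation (Q2, Lin's concordance), and Nash-Sutcliffe /
    factor-of-N model evaluation, plus seeded synthetic-data generators for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
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
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
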