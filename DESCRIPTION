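Package: greycast
Title: Grey-Markov Forecasting for Short Multivariate Count Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Grey-system forecasting for short, fluctuating incidence count
    panels (four to a dozen annual observations): grey relational analysis
    with Deng's distinguishing coefficient for factor screening, the
    single-variable GM(1,1) model, factor-driven and fully coupled
    multivariate grey models with continuous-time solutions, Markov-chain
    residual-state correction of fitted and forecast values, and a
    MAPE/MAE/RMSE evaluation framework with model-dimension selection.
    Ships the Michigan roundabout crash panel (2016-2021) used throughout
    the documentation, seedable synthetic-panel generators with known
    ground truth, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
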