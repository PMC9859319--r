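Package: reeforecast
Title: Forecasting Regional Public-Health Demand from Eco-Efficiency
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Panel forecasting of five regional hospital-activity indicators
    (visits, emergency outpatients, inpatients, health examinations,
    discharges) from regional eco-efficiency and economic, demographic and
    medical-supply covariates.  Eco-efficiency is computed with a
    slacks-based-measure (SBM) data envelopment analysis model with
    undesirable outputs, solved as a single linear program per unit via the
    Charnes-Cooper transform.  Forecasts use least-squares support vector
    regression with a radial basis kernel, the dual system solved exactly,
    with hyperparameters (sigma, gamma) chosen by a stochastic
    accept-if-no-worse search.  Includes a seeded synthetic panel generator,
    out-of-sample error metrics (MPE, MSE, SDE), forecast-stability
    summaries, and table rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    boot,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
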