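Package: ch4meta
Title: Meta-Analytic Development and Evaluation of Enteric Methane Prediction Equations for Cattle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for meta-analytic modelling of enteric methane (CH4) output in
    beef and dairy cattle from treatment-mean records. Harmonizes heterogeneous
    literature records through an energy-balance and digestibility calculus
    (gross-energy intake from diet chemistry, DE/ME balance, feeding level,
    digestibility imputation and adjustment to the maintenance feeding level,
    CH4 unit conversion), generates calibrated synthetic treatment-mean
    databases with study-level clustering, houses a registry of published and
    database-derived prediction equations, fits weighted linear and nonlinear
    mixed-effects prediction models with study random intercepts and slopes,
    and evaluates equations by mean squared prediction error decomposition
    (mean, slope and random components) and Lin's concordance correlation
    coefficient.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    nlme,
    lmerTest,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
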