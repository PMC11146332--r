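Package: evatcrop
Title: Quasi-Fuzzy Neural Estimation of Daily Reference Evapotranspiration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates daily reference evapotranspiration (ET0) from limited
    meteorological inputs with a hybrid quasi-fuzzy neural model. Numeric
    weather variables are fuzzified into low/medium/high triangular
    memberships, an exhaustive rule base is fired with the product t-norm,
    and the normalised firing strengths feed one-hidden-layer neural
    regression heads trained by L-BFGS, one head per input combination.
    Includes a daily FAO-56 Penman-Monteith engine used as the supervised
    target, the evaluation metrics (R2, Willmott's d, RMSE, RMSRE and their
    averages), a seasonal synthetic weather generator, and decision-tree and
    neural-network baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    rpart,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
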