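Package: lcmob
Title: Life-Course Socioeconomic Mobility and Stroke Risk in Matched
    Case-Control Studies
Version: 0.1.0
Authors@R:
    person("lcmob", "maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for life-course socioeconomic analyses of ischemic stroke
    risk in frequency-matched case-control studies. Implements additive
    socioeconomic risk scores for childhood, adolescence and adulthood,
    control-tertile risk strata, intergenerational occupational and
    score-stratum social-mobility classification, exact conditional logistic
    regression for age-band by sex matched strata (recursive computation of
    the conditional likelihood with analytic derivatives, Newton-Raphson
    fitting, Wald odds-ratio intervals), a full analysis pipeline producing
    mobility tables with three nested adjustment models, and a synthetic-data
    generator with a Gaussian-copula latent socioeconomic trajectory so every
    stage can be exercised and calibrated without access to individual-level
    study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
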