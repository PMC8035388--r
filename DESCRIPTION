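Package: workloadcv
Title: Short-Timescale Cognitive-Workload Prediction from Task Events
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a multi-UAV refuelling task performed together with a
    detection response task (DRT), constructs per-trial predictors of
    momentary cognitive workload from recent task events (windowed event
    flags and counts, an order-p power mean of on-screen fuel levels, the
    rank of the last-checked UAV's fuel, and previous-trial omission), and
    evaluates them with between-subject cross-validated model selection over
    mixed-effects models (linear, binomial, Poisson, two-part log-normal and
    zero-inflated Poisson families) scored by normalized mean squared
    deviation. Includes AIC/BIC comparison ladders, effect-size reports and
    a power-mean exponent sensitivity sweep.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    glmmTMB,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
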