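Package: dnrflux
Title: Day-Night Resolved Ecosystem Respiration from Eddy-Covariance Flux Partitioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a daytime flux-partitioning model with a relative-humidity
    respiration modifier (DT-RH) to half-hourly eddy-covariance records in
    moving windows, estimating separate daytime and nighttime apparent
    temperature sensitivities (E0,day and E0,night) of ecosystem respiration
    by Markov chain Monte Carlo. Provides the classical nighttime (NT) and
    daytime (DT) partitioners as baselines, monthly aggregation of E0 and the
    day-night ratio dE0 with seasonal amplitude and coefficient-of-variation
    statistics, latitudinal/climate-space binning, driver attribution via
    principal components, AICc-ranked linear models and random-forest
    permutation importance, and a synthetic flux-tower generator that serves
    as ground truth for parameter-recovery experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    minpack.lm,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
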