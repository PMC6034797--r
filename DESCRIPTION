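Package: herringmse
Title: Food-Web Modelling and Management Strategy Evaluation for Pacific
    Herring Fisheries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and solves static mass-balanced trophic food-web models
    of a herring-centric Northeast Pacific shelf ecosystem, projects them
    forward in time with foraging-arena trophic dynamics under fishing
    mortality schedules and climate (primary-productivity) forcing, and runs
    closed-loop management strategy evaluation (MSE) of herring harvest
    control rules with stochastic stock-assessment error.  Evaluation
    metrics include grand-mean biomass changes against an unfished baseline,
    a lower-quartile risk statistic, fishery closure and stock collapse
    probabilities, mean trophic level and Shannon-Wiener diversity of the
    food web, and herring catch summaries.  A deterministic synthetic
    reference web and phytoplankton anomaly series generator make every
    analysis reproducible without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
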