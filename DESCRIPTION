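Package: rmlcontrol
Title: Meta-Reinforcement Learning Simulations of Cognitive Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.net", role = c("aut", "cre"))
Description: Simulates a meta-reinforcement-learning agent in which the
    intensity of cognitive control (a discrete 'boost' signal) is itself
    learned by reinforcement to maximize net value, i.e. reward discounted
    by the intrinsic cost of control. The boost signal drives simulated
    locus coeruleus (LC) and ventral tegmental area (VTA) outputs that
    modulate task-specific modules: a drift-diffusion accumulator for
    speeded two-option decisions and explore/exploit foraging choices, and
    a competitive recurrent network for verbal working memory. Option
    values are tracked by scalar Kalman filters. Includes the three task
    environments (a 6x6 reward-grid speeded decision task, a verbal
    working-memory task at loads 1/4/6/8, and a 16-context x 8-bandit
    foraging task), a reproducible experiment runner, and an analysis
    pipeline that turns trial logs into simulated dorsal anterior
    cingulate (dACC) activity profiles with polynomial AIC model
    comparison, Akaike weights, linear-trend t tests and a repeated
    measures load ANOVA.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
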