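Package: crowdsolve
Title: Evolutionary Agent-Based Simulation of Collective Problem Solving
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Stochastic evolutionary simulator of crowdsourced problem
    solving. A population of N players is divided into groups of size S;
    in every iteration each player either joins the group's collectivists
    (with an individual probability p) and attempts a task of simplicity R,
    or works alone on a G-times-harder task for a private payoff G. Groups
    accumulate capacity (iterations in which at least one collectivist
    solved), players accumulate fitness, and rounds end with fitness-based
    replacement of below-average players. The package provides the engine,
    grid experiments over (S, R) producing collaboration/fitness/capacity
    surfaces, an analytic mean-field comparison of collectivist and
    free-rider payoffs, and closed-form oracles that certify the stochastic
    engine at small scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
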