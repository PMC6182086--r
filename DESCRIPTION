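Package: plasticrnn
Title: Weight-Change Localization in Recurrent Network Models of Prefrontal Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Trains four families of recurrent neural-network models of
    prefrontal cortex (Hessian-free-objective, Dale's-law gradient,
    actor-critic reinforcement, and reward-modulated Hebbian networks) on a
    context-dependent sensory integration task, and analyses where learning
    changes synaptic weights: per-postsynaptic-unit mean absolute weight
    changes, distribution statistics (Shapiro-Wilk, moment-based skewness and
    kurtosis Z-tests), rank-ordered unit-inactivation sweeps with two-way
    ANOVA and Tukey post-hoc comparisons, and network-size sweeps with
    Kruskal-Wallis and Dunn tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
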