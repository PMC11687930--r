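Package: recollect
Title: Gated Recurrent Working-Memory Networks Trained with Local Synaptic Tags and Traces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Implements a light-gated recurrent working-memory network trained
    by a strictly local reinforcement-learning rule based on synaptic traces
    and tags under SARSA(lambda) temporal-difference learning. Includes the
    pro-/anti-saccade and two-armed reversal-bandit task environments,
    training and evaluation protocols (convergence criteria, optimal-pull
    fractions, cumulative regret, serial-reversal schedules), unit-selectivity
    analyses with regression diagnostics and a robust fallback, and a
    finite-difference oracle verifying that the local trace/tag machinery
    reproduces backpropagation-through-time gradients of the selected
    action value.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    MASS,
    lmtest,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
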