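Package: telic
Title: Telic State Representations for Goal-Directed Agents
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Constructs goal-equivalence classes ("telic states") over the
    experience distributions induced by one-dimensional Gaussian random-walk
    policies, measures policy complexity as Kullback-Leibler divergence from a
    default policy, computes information projections of the default policy onto
    telic states, tests telic controllability under a capacity bound, and
    repairs unreachable representations by inserting intermediate waypoint
    states.  Includes complexity-granularity and goal-complexity tradeoff
    curves, YAML/JSON scenario configuration with a small command-line driver,
    and ggplot2 visualisations.  All user-facing functions take data frames of
    policies first and return tibbles, so analyses compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
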