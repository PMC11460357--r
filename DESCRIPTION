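Package: receptr
Title: Exposure and Receptivity to News Articles on Social Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates how many social-media users are both exposed to and
    receptive to believing specific news articles, by combining observational
    sharing data with survey-based belief rates. Reconstructs time-inferred
    retweet cascades from tweet tables and follower networks, imputes
    continuous user ideology with a two-stage Bayesian model (population
    normal, per-sharer skew normal, fitted by a built-in No-U-Turn sampler),
    converts shares into per-follower exposure events through a truncated
    normal viewing-delay model, and computes receptive-exposure estimates
    r_j = sum_i x_ij * p_ij from ideology-binned exposure counts and survey
    belief proportions. Includes a data-driven simulator of platform
    interventions (fact-check labels, sharing friction, visibility reduction)
    with configurable deployment delay, and a seed-controlled synthetic data
    generator for homophilous follow graphs, sharing cascades, and surveys.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rjags,
    coda,
    optparse
Config/testthat/edition: 3
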