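Package: pcpgame
Title: Game-Theoretic Modelling and Simulation of the Perceptual Crossing Paradigm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models each encounter in the two-person Perceptual Crossing
    Paradigm (PCP) as a choice between engaging less ('L') and engaging more
    ('M') with an unknown object on a shared one-dimensional ring. Implements
    the per-encounter detection probabilities under mixed engagement
    strategies, the constant-time-cost comparison of the two strategies via
    geometric compounding, the benefit landscape over engagement and
    interaction-gain parameters, the critical interaction-gain threshold, and
    the derived symmetric 2x2 game with pure-strategy Nash enumeration,
    ordinal ranks and Assurance/Prisoner's-Dilemma classification. Also ships
    an agent-based simulator of the PCP world (avatars, private static
    objects, shadow lures, binary haptic contact) that estimates the
    detection probabilities from first principles and checks the model's
    assumptions end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
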