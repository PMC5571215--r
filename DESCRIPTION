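Package: riskfix
Title: Evolution of Risk Preference Under Alternative Reproduction Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of competition between a risk-averse and a
    risk-prone behavioural strategy in a haploid population of constant size with
    non-overlapping generations. Individuals accumulate payoffs over a fixed number
    of lifetime decision events; the risk-averse strategy earns a constant payoff
    per event while the risk-prone strategy earns a high or a low payoff at random,
    with the two strategies matched in mean. Reproduction follows one of several
    payoff-to-fitness mappings (proportional, rank-based truncation,
    absolute-threshold truncation, power-weighted, and sigmoid-weighted selection),
    and each run proceeds to fixation of one strategy. The package provides
    replicate management with deterministic seeding, an exact absorbing
    Markov-chain oracle for small populations, Wilson intervals and proportion
    z-tests for fixation probabilities, a registry of ready-made experimental
    scenarios, and tipping-point location along selection-parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
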