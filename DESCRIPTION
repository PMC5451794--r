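Package: boldsim
Title: Boldness-Driven Leadership in Repeated N-Player Snowdrift Foraging Games
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Seeded, configurable simulator of an evolutionary foraging game in
    which a group of agents repeatedly removes obstacles of varying difficulty.
    Each agent carries a personality trait, boldness, that sets the rate of its
    exponentially distributed decision time; the agent with the shortest decision
    time initiates the collective action, the remaining agents join as followers
    or abstain as free-riders, payoffs follow an N-player snowdrift game, and the
    initiator's boldness is updated by a reinforcement rule driven by task success.
    Includes an empirical success-probability environment, a reference model
    without personality traits, replicate sweeps over the update rate and task
    difficulty, summary statistics (cooperator and bold counts, initiator shares,
    a diversity index, decision times, costs and pay-offs over a trailing
    statistics window), and CSV/JSON serialization of complete task records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
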