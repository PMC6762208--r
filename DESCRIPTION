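Package: latentstate
Title: Online Latent-State Learning Models of Classical Conditioning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An online latent-state reinforcement-learning agent for
    classical conditioning: Rescorla-Wagner associative-strength updates
    indexed by latent states, an approximate Bayesian filter over states,
    belief- and effort-matrix-dependent associability, pooled prediction-error
    variance tracking, change-point-triggered creation of new latent states,
    and temporal/spatial context-shift mechanics including rumination. Ships
    a constant-associability Rescorla-Wagner baseline, programmatic builders
    for eleven classic conditioning experiment designs (blocking,
    overexpectation, conditioned inhibition, Hall-Pearce, Rescorla 2000
    compound conditioning, partial reinforcement extinction, backwards
    blocking, renewal, spontaneous recovery, and post-retrieval memory
    modification), directional effect checks over simulated trajectories,
    and a command-line interface with YAML/JSON configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
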