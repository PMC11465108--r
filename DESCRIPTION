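Package: cibo
Title: Cost-Informed Bayesian Optimization for Reaction Yield Campaigns
Version: 0.1.0
Authors@R: person("cibo", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Batch Bayesian optimization over discrete reaction design spaces
    in which the acquisition value of each candidate experiment is penalized
    by the current, inventory-dependent price of the reagents it requires.
    Provides a Gaussian-process surrogate with a Jaccard-Tanimoto kernel over
    reagent fingerprints, Monte-Carlo noisy expected-improvement acquisition,
    a dynamic inventory ledger that charges each compound purchase exactly
    once, campaign orchestration (cost-informed, standard, and random
    policies), synthetic benchmark generators emulating high-throughput
    experimentation yield tables, and a command-line interface for running
    and comparing campaigns.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
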