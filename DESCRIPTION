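Package: minimsim
Title: Minimisation Treatment Allocation and Predictability-Imbalance Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Pocock-Simon marginal-total minimisation algorithm for
    covariate-adaptive treatment allocation in randomised clinical trials, with a
    configurable probability P of allocating to the arm with the smallest marginal
    score (the "random twist"). Every allocation is classified as a tie (resolved
    by simple randomisation), deterministic (predictable with certainty by an
    observer who knows the algorithm and all prior allocations) or a random twist.
    A Monte-Carlo engine simulates replicate trials over grids of designs and P
    values, estimating allocation predictability and the probability of
    treatment-arm and within-factor baseline imbalance, and recommends the
    smallest P that preserves balance for a given trial design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    parallel,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
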