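Package: beliefsim
Title: Sequential Bayesian Belief Updating Under Confirmation Bias
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates how decision-makers with different prior beliefs revise
    their confidence that one of two treatments is superior as randomized
    trial evidence accumulates, with and without confirmation bias. Belief is
    updated in odds form, multiplying prior odds by each trial's likelihood
    ratio; confirmation bias is modeled as an exponent weight below one on the
    likelihood ratio of disconfirming evidence, classified against the current
    belief. Includes evidence-stream generators (constant, mixed-direction,
    and generative two-arm binomial trials), calibration tools that invert
    endpoints to implied likelihood ratios or bias factors, archetype
    comparison scenarios, bias and prior sweeps, evidence-order experiments,
    a YAML/JSON configuration layer, and plotting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
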