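Package: neuralwm
Title: Efficient-Coding Neural Resource Models of Visual Working Memory
Version: 0.1.0
Authors@R:
    person("Analysis", "Team", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and fitting tools for population-coding models of
    continuous-report visual working memory. Implements a heterogeneous
    von Mises population code warped by a circular stimulus prior
    (efficient coding), divisive normalization across set size, Poisson
    spiking, and Bayesian posterior-mean decoding; an extended
    slots-plus-averaging competitor with stimulus-specific precision and
    bias modulation; Monte-Carlo stimulus-response-matrix maximum
    likelihood fitting with AIC comparison; kernel-smoothed circular
    bias and precision curves; a von Mises plus uniform contamination
    mixture for block-wise bias estimation; and generators for synthetic
    observers and nontarget-distribution adaptation experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
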