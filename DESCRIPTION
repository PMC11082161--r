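Package: striatoseq
Title: Spiking Corticostriatal Sequence Learning with Anti-Hebbian Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates striatal medium spiny neurons (leaky integrate-and-fire
    and adaptive quadratic models) driven by spatio-temporal cortical spike
    patterns, with pair-based spike-timing-dependent plasticity (Hebbian and
    anti-Hebbian, symmetric and asymmetric) combined with non-associative
    reward potentiation. Provides generators for four families of
    spike-sequence classification tasks, training and frozen-weight test
    protocols for single neurons and two-neuron circuits with collateral
    inhibition, accuracy metrics, a closed-form theory of premature-spike and
    missed-spike error modes, and a nonnegative-weight logistic-regression
    baseline classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    optparse
Config/testthat/edition: 3
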