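Package: netstab
Title: Stabilizing Structured Recurrent Networks Through Node Self-Coupling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Monte-Carlo pipeline for studying how negative self-coupling of
    the nodes stabilizes recurrent networks with structured topology.
    Generates random interaction matrices with small-world (exact-count
    Watts-Strogatz rewiring), scale-free (preferential attachment with
    +1-smoothed attachment kernel), Kronecker self-similar, and
    Erdos-Renyi topologies; tests asymptotic stability from the eigenvalue
    spectrum; estimates the probability of stability with binomial error
    measures; fits Hill functions to stability transitions to extract the
    stabilization parameter at which half of the trials are stable; and
    fits the power-law dependence of that parameter on network size.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    methods,
    minpack.lm,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
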