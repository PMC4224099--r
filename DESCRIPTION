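Package: percmem
Title: One-Shot Hetero-Associative Memory with Bootstrap-Percolation Retrieval
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulation and analytic theory for a one-shot hetero-associative
    memory in sparse random networks: stochastic binary Hebbian learning with
    palimpsest pruning on afferent connections between two neuronal
    populations, combined with Willshaw-style clipped recurrent connections
    and first-spike iterative retrieval modelled as bootstrap percolation
    under a K-threshold activation rule. Provides closed-form signal/noise
    edge probabilities, binomial degree distributions, admissible threshold
    windows, percolation-threshold solvers, capacity predictions and optimal
    plasticity, together with Monte Carlo capacity measurements, parameter
    sweeps, noise-tolerance experiments and an error-decomposition study
    comparing simulation against the theoretical predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
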