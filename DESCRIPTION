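Package: snapkin
Title: Snapshot Kinetic Analysis of Nanopore RNA Folding Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs RNA folding pathways from single-molecule nanopore
    "snapshot" experiments. Simulates folding/unfolding event data from a
    five-state continuous-time Markov scheme (single-stranded, hairpin
    intermediates, misfolded and native pseudoknot states), builds log-binned
    unfolding-duration histograms and fits them with log-time exponential
    mixtures (globally across folding times), converts component amplitudes to
    time-resolved fractional state populations, and recovers transition rate
    constants by master-equation fitting with multi-start optimisation.
    Includes tools to segment synthetic multi-level current traces into
    blockade plateaus and classify unfolding signatures.
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
    Matrix,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
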