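Package: biasim
Title: Simulation of Main-Effect and Taxon-Taxon Interaction Bias in
    Microbiome Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generates marker-gene read-count datasets subject to
    taxon-specific experimental bias and taxon-taxon interaction bias
    under a multiplicative (log-linear) bias model, together with a
    benchmarking harness for compositional differential-abundance
    methods: Dirichlet-Multinomial community simulation with trait and
    confounder spike-ins, rare-taxon presence filters, Wilcoxon
    rank-sum tests on additive log-ratio transformed counts with
    Benjamini-Hochberg adjustment, an adapter registry for external
    methods, and replicate grids reporting empirical false discovery
    rate and sensitivity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
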