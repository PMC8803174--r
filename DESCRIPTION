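Package: grnmc
Title: Multicanonical Sampling and Evolutionary Simulation of Gene
    Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for exploring the genotype space of a discrete-time
    gene regulatory network (GRN) model with signed directed edges and a
    sigmoidal response function.  A Wang-Landau / multicanonical Monte
    Carlo engine builds a flat-histogram reference ensemble of networks
    spanning all fitness levels and estimates the genotypic entropy (the
    per-fitness-bin appearance probability of genotypes under uniform
    random sampling, down to exponentially rare high-fitness classes).
    Truncation-selection evolutionary simulators (Evo50/Evo90) with
    lineage tracing provide the evolved counterpart.  Comparative
    analyses include mutational robustness by single-edge deletion,
    essential-edge and effective-node counts, bistability and hysteresis
    detection with switch classification, simple-path and signed network
    motif censuses, and sub-bin histogram reweighting for matched-fitness
    comparisons between ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
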