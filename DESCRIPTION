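Package: traitnet
Title: Correlation-Network Analysis of Plant Functional Trait Coordination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for studying coordination among plant functional
    traits as a correlation network. From species-mean trait tables it
    derives traits from organ measurements, log10-transforms and
    size-corrects them against total plant biomass, computes
    pairwise-complete Pearson correlation matrices with per-pair sample
    sizes, builds significance-thresholded trait networks, detects trait
    modules by spin-glass simulated annealing with Newman-Girvan
    modularity, scores trait importance as the first principal component
    of degree, betweenness and closeness centrality, and compares two
    sites via the Fisher r-to-z test for independent correlations.
    Includes phylogenetically independent contrasts (unit branch lengths,
    random polytomy resolution) and a synthetic-data generator with
    planted module structure, Brownian-motion phylogenetic signal,
    allometric size dependence and block-structured missingness for
    ground-truth benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
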