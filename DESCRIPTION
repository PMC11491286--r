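Package: mesocortex
Title: Mesoscale Connectome Construction and Spiking Simulation of Human Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a layer- and population-resolved synapse-count connectome
    ("mesoconnectome") for the 34 areas of one hemisphere of human cortex in the
    Desikan-Killiany parcellation from tabular anatomical data (layer thicknesses,
    neuron volume densities, surface areas, diffusion-tractography streamline and
    fiber-length matrices, a local-circuit blueprint, and dendritic morphology
    profiles), supplemented by predictive connectomics for the laminar origin
    (SLN) and target patterns of long-range projections. Realizes the connectome
    as an explicit network of leaky integrate-and-fire neurons with exponential
    postsynaptic currents and simulates it with a deterministic compiled engine
    that supports exactly paired perturbation runs. Ships the accompanying
    analysis suite: spike-train statistics (rates, CV ISI, revised local
    variation), Kolmogorov-Smirnov similarity, a functional-connectivity proxy
    from summed synaptic currents, temporal-hierarchy estimation from
    cross-correlations, single-spike perturbation tracking, and graph metrics,
    plus a synthetic-anatomy generator so the whole pipeline runs without any
    data download.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    igraph,
    jsonlite,
    yaml,
    optparse,
    pracma,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
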