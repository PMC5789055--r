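Package: spineclust
Title: Dendritic Spine Turnover, Clustered Structural Plasticity, and a
    Tagging-and-Capture Network Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistics for longitudinal dendritic-spine imaging data
    (turnover ratios, 5-micron clustering of newly formed spines,
    nearest-neighbour distances, survival of clustered versus non-clustered
    spines, fear-learning behavioural metrics), four Monte-Carlo/permutation
    null models for spatial clustering along dendrites with Gaussian fits and
    empirical p-values, a synthetic spine-map generator with hotspot
    enrichment for testing the full analysis chain without in-vivo data, and
    a biophysically inspired network simulator (integrate-and-fire somata
    with 20 dendritic subunits, synaptic tagging and capture,
    plasticity-related proteins, homeostatic scaling, stochastic synaptic
    turnover) with engram readouts: same-subunit synapse-pair clustering
    fractions and Treves-Rolls population sparsity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
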