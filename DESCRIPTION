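Package: tractnet
Title: Structural Connectomes from Probabilistic Tractography Streamline
    Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Construction and graph-theoretic analysis of binary structural
    connectomes from probabilistic-tractography visitation counts. Provides
    Monte Carlo streamline propagation over synthetic fibre-orientation
    fields, pairwise maximum-visitation extraction, a Poisson-tail
    individual threshold, group-consensus thresholding across subjects, and
    from-scratch binary-graph measures: degree, Brandes betweenness,
    closeness, local clustering, and modularity-based module detection
    (Newman spectral bisection with Kernighan-Lin refinement, and Louvain).
    Ships a transcription of published group connection-probability
    matrices for a 43-region fronto-temporo-parietal cortical network,
    together with tools to rerun the network analysis on them and compare
    against the published per-node metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    RNifti,
    stats,
    tools,
    utils
Suggests:
    igraph,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
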