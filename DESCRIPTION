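Package: foldbias
Title: Vertex-Spacing Bias in Surface-Based Functional MRI
Version: 0.1.0
Authors@R: person("foldbias", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to quantify and demonstrate how uneven vertex spacing on
    folded cortical surface meshes induces spurious correlations in
    surface-based fMRI (the "gyral bias"). Provides mesh geometry primitives
    (adjacency, inter-vertex distance, vertex areas, truncated geodesic
    distances), a synthetic folded-cortex generator whose vertex spacing
    covaries with sulcal depth, the two bias mechanisms (volume-to-surface
    projection and geodesic Gaussian smoothing), local-correlation
    statistics, area-weighted association tests with a spatial shift
    permutation null, contiguity-constrained Ward parcellation, and
    connectome fingerprinting with geodesic distance thresholding.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
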