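Package: netsync
Title: Between-Network Synchronization Analysis for Resting-State fMRI
Version: 0.1.0
Authors@R: person("NCODE", "Imaging Tools", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for between-network synchronization analysis of
    resting-state fMRI: temporal preprocessing (nuisance regression, low-pass
    filtering below 0.08 Hz), temporally concatenated group spatial independent
    component analysis, goodness-of-fit matching of components to network
    template masks, dual regression to subject-specific network time courses
    and spatial maps, inter-network Pearson correlation statistics with
    Monte-Carlo cluster-size correction on the network-pair graph, voxelwise
    permutation tests, and brain-behavior correlations. Includes a synthetic
    4D phantom generator that plants known network structure, group-specific
    inter-network correlation matrices, confounds and behavior effects, plus
    minimal NIfTI-1 input/output.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
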