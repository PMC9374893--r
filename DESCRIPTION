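Package: sparsewmh
Title: Cross-Resolution White-Matter-Lesion Segmentation with a Spatially Sparse Loss
Version: 0.1.0
Authors@R:
    person("Sparse WMH", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Trains high-resolution 3D T1-space white-matter-lesion segmenters
    from sparse, thick-slice 2D FLAIR-space target masks. Provides voxel-grid
    geometry and resampling, the FLAIR-to-T1 voxel-center sampling map and the
    spatially sparse cross-resolution loss, U-shaped convolutional networks with
    index-preserving unpooling and instance normalization, a loss-ranked two-step
    training-set curation workflow, periventricular/deep/juxtacortical region
    partitioning, DICE evaluation in target space, and a synthetic paired-resolution
    phantom generator for end-to-end testing without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
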