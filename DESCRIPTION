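Package: rootfill
Title: Scale-Adaptive Flood-Fill Segmentation of Plant Root Systems in 3D CT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for segmenting plant root systems in 3D X-ray computed
    tomography volumes with a scale-invariant voxel classifier and a
    flood-filling inference that locally adapts its field of view. Provides
    sub-label-balanced patch sampling from weak label volumes, a 3D
    convolutional classifier with a spatial pyramid pooling layer that
    accepts cubic patches of arbitrary edge length, a weakly supervised
    relabeling loop with a cosine-annealing learning-rate schedule, dynamic
    flood-fill inference with growing, field-of-view reduction and pruning
    phases, a naive voxel-wise baseline with connected-component filtering,
    and set-algebra comparison of segmentations. A synthetic root-phantom
    generator (branching root tubes in inhomogeneous soil with pebble
    distractors, pot wall and air) makes the whole pipeline testable
    without CT data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
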