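Package: surftrack
Title: Topological Object Segmentation and Tracking via Local Diffeomorphisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Segments and tracks moving textured objects in image sequences
    using a purely geometric criterion: two image patches taken from
    successive frames belong to the same surface exactly when they are
    related by a local diffeomorphism, approximated here by a six-parameter
    affine transform recovered by Newton iteration on Gabor place tokens.
    Edges are classified as texture or occluding contours by comparing the
    affine transforms found on either side; occluding contours are assigned
    a border owner by an accretion test; texture edges are erased to turn a
    super segmentation into an object segmentation; and components are
    linked across frames into a scene graph whose connected components are
    invariant objects.  Includes a layered synthetic-scene generator with
    per-frame ground truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
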