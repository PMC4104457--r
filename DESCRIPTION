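Package: vfinger
Title: Virtual-Finger 3D Pinpointing, Curve Tracing and ROI Generation
    for Volumetric Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps single 2D screen gestures (clicks, strokes, zooms) into 3D
    points, curves and regions of interest inside volumetric microscopy
    stacks. Implements progressive mean-shift point pinpointing for
    multi-channel and noisy images, intensity-weighted geodesic curve
    drawing by fast marching on the voxel graph (basic, globally optimal
    and bounding-box-restricted variants), a resampled curve-to-curve
    spatial-divergence metric, multi-resolution octree pyramids for stacks
    too large to load whole, and a deterministic synthetic phantom
    generator (tubes, helices, blobs, occluders) with analytic ground
    truth for validation. Volumes are read and written as multi-page TIFF,
    NRRD or raw+JSON; curves as SWC; landmarks as marker CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
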