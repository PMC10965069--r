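Package: bundletrack
Title: Tracking and Strain Analysis of Beating Cardiac Microbundle Movies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic analysis of time-lapse movies of beating cardiac
    microbundles. Provides tissue-mask segmentation, auto-tuned sparse
    optical-flow tracking of fiducial markers (Shi-Tomasi corner detection
    plus a pyramidal Lucas-Kanade solver), temporal segmentation of
    individual beats with per-beat drift correction, subdomain-averaged
    deformation gradients and Green-Lagrange strains estimated by pairwise
    least squares, micropillar deflection-to-force conversion, and a
    synthetic beating-movie generator with exact analytic ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    interp,
    jsonlite,
    Rcpp,
    tiff,
    grDevices,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
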