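Package: autoffr
Title: Automatic Fractional Flow Reserve from Coronary CT Angiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automatic workflow from a coronary CT angiography volume to
    computed fractional flow reserve (cFFR). Provides per-slice image
    filtering (non-local means de-noising, Frangi vesselness, binary
    thresholding with contour-area removal), unsupervised coronary lumen
    segmentation by density clustering (DBSCAN) anchored on a Hough-circle
    aortic landmark, centreline extraction by 3D thinning with lumen radius
    estimation from an iso-surface, resampling to an equidistant 1D mesh,
    and an implicit coupled 1D-0D pulsatile blood-flow solver with coronary
    Windkessel outflow beds and Murray-law flow distribution. Includes
    digital vessel phantom generators with known ground truth for every
    pipeline stage and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    graphics,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
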