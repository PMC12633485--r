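Package: tomopick
Title: Unsupervised Particle Picking in Cryo-Electron Tomograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Template-free localization of macromolecular particles in
    cryo-electron tomograms. Per-voxel features are extracted from cubic
    neighborhoods (raw intensities, 3D discrete Fourier transform
    magnitudes, or a bank of 3D Gabor filters), clustered into particle
    and background classes with k-means or a Gaussian mixture model, and
    converted to particle instances by connected-component labeling or
    marker-based watershed segmentation. Geometric instance centroids are
    the predicted particle positions. Includes MRC2014 volume input and
    output, coordinate-set evaluation (precision, recall, F1 at a
    distance threshold, and recall relative to a Monte-Carlo random
    baseline), and a synthetic phantom generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
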