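Package: tomopick
Title: Transformer-Based Macromolecule Particle Picking in Cryo-Electron Tomograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for localizing and classifying macromolecular
    particles in reconstructed cryo-electron tomograms. Provides MRC volume input
    and output with full spatial metadata, tomogram standardization (isotropic
    resampling, percentile normalization, label remapping), multi-scale volumetric
    feature extraction (difference-of-Gaussians blobness, Sobel gradient magnitude,
    morphological top-hat contrast), context-padded subvolume gridding with exact
    stitching, a three-dimensional shifted-window transformer U-Net for voxel-wise
    segmentation trained with class-weighted cross-entropy, and post-processing
    that converts dense predictions into particle centroids scored by one-to-one
    Hungarian matching. A synthetic tomogram simulator with known ground truth
    supports development and validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
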