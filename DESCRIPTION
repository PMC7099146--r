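Package: dualpathseg
Title: Dual-Pathway CNN Segmentation of Brain Regions in Volumetric
    Micro-Optical Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated segmentation of brain regions in volumetric
    micro-optical images (nominal 10 micrometre isotropic, coronal slices)
    by a patch-based dual-pathway convolutional neural network that fuses
    local and contextual features from two co-centred receptive fields.
    Global localization is supplied by multi-resolution mutual-information
    registration of an average-intensity atlas (affine plus a symmetric
    diffeomorphic nonlinear stage), label propagation and morphological
    dilation of the middle slice (Mask-init), and then by slice-to-slice
    tracking in which each segmented slice, dilated, constrains prediction
    on its neighbours (Mask-track). Includes class-balanced two-scale patch
    sampling with intensity augmentation, masked interval prediction,
    3D postprocessing, segmentation and localization metrics, a synthetic
    phantom generator with cell-like texture and controlled slice-to-slice
    shape drift for validation, and TIFF/NIfTI volume input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    RNifti,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
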