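Package: rcnnseg
Title: Recurrent Slice-Sequence Segmentation of 3D CT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for 3D segmentation of tubular, anatomically connected
    structures (such as the mandible) in CT volumes by a recurrent
    encoder-decoder network: each slice is segmented by a shared 2D U-Net-style
    unit that receives the previous slice's predicted probability map through a
    learned recurrent transform, so the whole scan is processed as a sequence
    of arbitrary length. Includes the compound Dice plus binary cross-entropy
    loss, end-to-end training by backpropagation through time with Adam and
    early stopping, classic 2D / 2.5D / 3D-patch feeding baselines, surface
    distance evaluation metrics (Dice coefficient, average symmetric surface
    distance, 95% and maximum Hausdorff distance) under anisotropic voxel
    spacing, NIfTI and NRRD volume input/output, and a parametric generator of
    mandible-like synthetic phantoms with noise and streak artifacts for fully
    reproducible experiments without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
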