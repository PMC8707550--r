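Package: augforge
Title: Image Data Augmentation Methods and Ensemble Harness for Biological Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Eleven label-preserving image data-augmentation procedures for
    training image classifiers on small biological and scientific image sets:
    geometric transforms (reflection, anisotropic scaling, rotation,
    translation, shear), subspace-coefficient perturbation in PCA and DCT
    bases, photometric manipulation (contrast stretching, sharpening, color
    shifting, HSV jitter, histogram specification, Reinhard color transfer),
    elastic deformation by raw and low-pass-filtered random displacement
    fields, and two transform-domain methods that perturb single-level Haar
    wavelet coefficients and column-wise constant-Q transform coefficients.
    Includes a seeded synthetic fixture generator, folder-per-class and CSV
    manifest image-set input/output, and a sum-rule ensemble harness that
    trains one classifier per augmentation method and fuses their softmax
    scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    png,
    tiff,
    EBImage,
    nnet,
    stats,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
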