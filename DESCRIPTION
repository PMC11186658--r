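Package: bucketaugment
Title: Q-Learning Search over Buckets of 3D Volumetric Augmentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated augmentation-policy search for 3D medical image
    segmentation. Random "buckets" of volumetric transforms (translation,
    rotation, zooming, elastic deformation, intensity, contrast, sharpening,
    smoothing, Gaussian noise, identity) are scored by a tabular Q-learning
    controller driven by validation-loss rewards inside the training loop;
    the highest-scoring bucket is the discovered policy. Includes the ten
    transforms with 15-bin magnitude grids, a TrivialAugment-style baseline
    sampler, a model-agnostic training harness with Dice and cross-entropy
    losses, a synthetic 3D phantom generator with controllable domain shift
    for fully offline testing, NIfTI input/output, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    RNifti,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
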