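Package: voxuq
Title: Segmentation Uncertainty Quantification and Propagation for Voxel Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies image-segmentation uncertainty from ensembles of
    co-registered 3D segmentation samples as voxel-wise probability maps,
    summarises it with normalized Shannon-entropy uncertainty maps, extracts
    nested percentile segmentations (including the three standard
    segmentations at the 15.9, 50.0 and 84.1 percentiles) and smooth
    level-set surfaces, propagates the segmentations through voxel
    finite-volume Laplace solves (volume fraction, effective transport,
    tortuosity), and estimates the resulting uncertainty distribution of
    physics quantities with a characteristic Normal distribution or
    alternative families. Includes a synthetic-scene generator with
    analytically known probability maps so every stage is testable, and a
    config-driven end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
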