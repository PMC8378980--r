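Package: ipsoseg
Title: Maximum-Entropy Image Segmentation with a Shrinkage-Factor Particle Swarm Optimizer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments bright target regions (such as the placenta in uterine
    magnetic resonance images) from single-channel gray-scale images by
    maximizing Kapur's inter-class entropy over the gray-level histogram with
    an improved particle swarm optimizer whose velocity update is damped by a
    linearly decreasing shrinkage (constriction) factor. Includes the
    surrounding preprocessing chain (linear contrast stretch, Gaussian
    smoothing, binarization, connected-component area filtering), an
    exhaustive-search oracle for the entropy objective, Jaccard evaluation of
    segmentations against reference masks, paired diagnostic-accuracy
    statistics (sensitivity, specificity, accuracy, McNemar's test), a
    synthetic phantom generator with known ground truth and graded invasion
    depth, and a two-fold cross-validation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
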