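Package: asariscan
Title: Estimating Buried Clam Distribution from 3D Acoustic Coring Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the presence, count, and spatial
    distribution of buried bivalves (asari clam, Ruditapes philippinarum)
    from three-dimensional reflection-intensity volumes produced by an
    acoustic coring system. Provides a physics-inspired synthetic volume
    generator for the four experimental bucket types, reflection-window
    detection and depth standardization, overlapping 25x25 local-voxel
    extraction with distance-based labeling from ground-truth positions,
    two small 3D convolutional neural network classifiers (presence and
    count) trained with Adam and early stopping, stratified group
    cross-validation with buckets as groups, classification metrics
    (accuracy, F1, ROC-AUC with macro averaging), bucket-level count
    integration with MAE/MRE/correlation, and Grad-CAM volumetric
    interpretation with depth-averaged panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
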