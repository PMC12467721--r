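Package: stcpose
Title: Semi-Supervised Temporal Context-Aware Pose Estimation for Swimming Fish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Heatmap-based animal pose estimation with soft-argmax sub-pixel
    decoding, extended for video by a bidirectional convolutional-recurrent
    five-frame fusion head and two unsupervised hinge losses: a temporal
    continuity loss on inter-frame keypoint displacement and a pose
    plausibility loss against a PCA-learned low-dimensional pose subspace.
    Labeled keypoint annotations (DeepLabCut CSV dialect) and unlabeled video
    clips are combined in a semi-supervised training loop. A synthetic
    articulated-fish video generator (carangiform undulation, three gaits,
    occlusion events, frame-synchronous ground truth) makes the whole method
    trainable and testable at desk scale on a single CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    png,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
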