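Package: phenotyper
Title: Semi-Automated Image-Based Phenotyping of Rosette Crops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for indoor high-throughput phenotyping of rosette crops such as
    Brassica napus from top- and side-view RGB and near-infrared (NIR) images.
    Provides colour-space threshold segmentation (HSV and CIELAB), holistic growth
    traits (projected leaf area, convex hull area, height, width, estimated
    biovolume, Excess Green Index, day-to-day deltas, outlier filtering), transfer
    of RGB plant masks onto NIR frames with intensity summaries, multi-scale
    boundary-shape descriptors (histogram of curvature over scale computed from the
    normalized area integral invariant), flower detection in the CIELAB blue-yellow
    channel with connected-component counting, anthesis calling, raceme-branch
    clustering, and a cross-validated machine-learning harness for raceme-branch
    regression and drought-stress classification. A synthetic-plant image generator
    with known ground truth makes the whole pipeline testable without an imaging
    facility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    class,
    e1071,
    grDevices,
    jsonlite,
    png,
    randomForest,
    rpart,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
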