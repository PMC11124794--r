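Package: poseclass
Title: Exercise Classification from 3-D Pose Landmarks with a Frame-Level
    CNN and Soft-Voting Ensemble
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies repetitive exercises (squats, curls, push-ups and
    seven other movements) from time series of 3-D body pose landmarks in
    the MediaPipe Pose convention. Each frame's 22 non-facial landmarks are
    turned into 78 attributes (66 raw coordinates plus 12 law-of-cosines
    joint angles), scored by a per-frame one-dimensional convolutional
    network, and per-frame class probabilities are pooled by soft voting
    over sliding windows (30 frames by default) into robust decisions.
    Includes a forward-kinematics skeleton-motion simulator that generates
    labelled landmark sequences with class-specific periodic joint-angle
    signatures, so the full pipeline can be trained, evaluated (stratified
    k-fold cross-validation, confusion matrices, accuracy-versus-window
    curves) and tested without any external data, plus readers and writers
    for landmark CSV/JSONL files and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    caret,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
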