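Package: fallfusion
Title: Multimodal Fall Detection by Audio-Video Decision Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects human falls in short clips by fusing two modalities at the
    decision level: a two-stream spatio-temporal graph convolutional network
    (ST-GCN) classifying 17-joint skeleton keypoint sequences, and a
    depthwise-separable convolutional network (MobileNetV2) classifying
    log-scaled mel spectrograms of the accompanying audio. Frame-level video
    scores are aggregated to clip level by a consecutive-frame rule, and the
    two modality probabilities are combined by linear weighting or by
    Dempster-Shafer evidence combination. Includes confusion-matrix metrics
    (sensitivity, specificity, accuracy, precision, F1), audio augmentation
    and k-fold cross-validation utilities, and a synthetic-data generator that
    emulates fall versus daily-activity kinematics and impact-transient versus
    ambient audio so the whole pipeline trains and tests without external
    recordings.
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
    signal,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
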