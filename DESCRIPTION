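Package: eegemotion
Title: Subject-Independent Emotion Recognition from Raw Multi-Channel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for emotion classification from raw multi-channel
    electroencephalogram (EEG) recordings without hand-crafted feature
    extraction. Continuous recordings are cut into overlapping fixed-length
    windows, each window is expanded to a convolutional-backbone-sized input
    tensor by Gaussian noisy-copy channel augmentation, normalized by per-row
    mean removal, and classified by a pluggable convolutional backbone followed
    by global average pooling and a stack of dense layers trained with Adam and
    early stopping. Predicted label sequences are smoothed with a categorical
    median filter. Includes leave-one-subject-out and cross-dataset evaluation
    harnesses, readers and writers for a portable recording container with
    SEED-, DEAP- and LUMED-style label conventions, and a synthetic EEG cohort
    generator with class-dependent spectral band signatures and per-subject
    distribution shift.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
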