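Package: saxlevel
Title: Slice-Level Classification of Cardiac Short-Axis Cine MRI Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying short-axis cardiac cine MRI slices into five
    ordered anatomical levels (out-of-apical, apical, mid, basal, out-of-basal)
    with a cascade of a frozen convolutional feature extractor and a
    many-to-many recurrent sequence classifier. Includes a synthetic cardiac
    phantom generator with ground-truth slice labels, dataset curation rules
    (duplicate identifiers, inconsistent phase slice counts, non-contiguous
    slice indices), subject-wise data splitting, LSTM/GRU sequence models
    trained with masked categorical cross-entropy and Adam, and an evaluation
    suite with per-class one-vs-rest F1, support-weighted AUC, accuracy,
    confusion matrices, an ordinal band statistic (SOTD) counting
    misclassifications that skip an adjacent level, and a merged three-class
    error rate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    withr,
    EBImage,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
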