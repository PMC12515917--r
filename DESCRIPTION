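Package: ctgkit
Title: Dual-Modal Cardiotocography Simulation, Digitization, and Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A toolkit for dual-modal (fetal heart rate plus uterine
    contraction) cardiotocography analysis. Simulates paired FHR/UC traces
    carrying the standard intrapartum event vocabulary (accelerations,
    early/late/variable decelerations, sinusoidal patterns, contractions)
    and renders them as two-band paper-style chart images; digitizes chart
    images back into standardized signals via thresholding, affine band
    templates, and masked column averaging; interprets records with a
    deterministic three-tier (Class I/II/III) rule engine; classifies chart
    images with a densely connected convolutional network carrying
    selective-kernel channel attention, trained with focal loss; and
    evaluates classifiers with a full confusion-matrix/ROC metric suite
    including a cross-center generalization decay rate.
License: MIT
Encoding: UTF-8
Imports:
    tibble,
    dplyr,
    purrr,
    tidyr,
    ggplot2,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    png,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
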