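Package: wearssl
Title: Domain-Knowledge-Guided Self-Supervised Contrastive Learning for
    Wearable Physiological Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-supervised contrastive representation learning for segmented
    wearable waveform data (ECG-like, EEG-like, accelerometry), guided by
    handcrafted domain features. Handcrafted descriptors (heart-rate
    variability, morphology, spectral band power, motion statistics) steer
    positive-pair selection through nearest-neighbour search in feature space
    and impose global structure through k-means prototypes updated by
    exponential moving average with per-cluster dynamic temperatures. Includes
    a seeded synthetic-signal generator with class-dependent rhythm and
    morphology and subject-dependent nuisance, a modality-agnostic
    augmentation pipeline, a compact 1-D residual convolutional encoder
    trained with a ramped combined instance- and prototype-level loss, and
    label-efficiency evaluation via KNN probing, linear probing and
    fine-tuning with balanced softmax cross-entropy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    nnet,
    signal,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
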