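Package: breathsae
Title: Breath Raman Spectrum Classification with Stacked Sparse Autoencoders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end computer-aided diagnosis pipeline for classifying
    breath Raman-like spectra into early gastric cancer, advanced gastric
    cancer and healthy classes. Provides a synthetic breath-spectrum cohort
    generator, spectral preprocessing (despiking, median filtering,
    asymmetric-least-squares baseline correction, Savitzky-Golay smoothing),
    wavenumber-shift data augmentation, fifty-peak feature extraction, a
    two-layer stacked sparse autoencoder with Kullback-Leibler sparsity
    penalty and softmax head trained by greedy layer-wise pretraining and
    supervised fine-tuning, and multiclass evaluation with confusion
    matrices, precision/recall/F-score, accuracy and one-vs-rest ROC/AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
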