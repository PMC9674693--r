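Package: echotype
Title: Automated Cell-Type Classification from High-Frequency Ultrasound Backscatter
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Label-free classification of single micron-sized objects (cells and
    cell-mimicking polystyrene microspheres) from one-dimensional backscattered
    high-frequency ultrasound signals. Provides a parametric forward model that
    synthesizes labeled pulse-echo datasets, a dilated one-dimensional
    convolutional denoising autoencoder with Gaussian-noise data augmentation,
    waveform, frequency-spectrum and spectrogram featurization, dilated 1D/2D
    convolutional classifiers with classical baselines (linear SVM, L2 logistic
    regression, multi-layer perceptron), and a stratified cross-validated
    evaluation harness with ablation and frequency-resolution sweeps. The neural
    networks are trained with a self-contained im2col/BLAS engine so the package
    has no deep-learning framework dependency.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    e1071,
    glmnet,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
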