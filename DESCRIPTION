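Package: cardiopatch
Title: Synthetic Single-Lead ECG Analytics with Interpretable Attention
    Models and Wear-Position Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for wearable single-lead electrocardiogram (ECG)
    analytics. Generates labelled synthetic ECG records with controllable
    pathology (arrhythmia, atrial hypertrophy, myocardial infarction),
    patch-orientation misplacement and noise structure; implements a
    preprocessing chain (power-line notch, band-pass, median-filter
    baseline correction, segmentation, per-window normalization),
    Pan-Tompkins QRS detection with heart-rate and heart-rate-variability
    reporting on 6-second windows, and signal-quality metrics (template
    SNR, baseline-drift amplitude, instantaneous frequency,
    cross-correlation). Provides an interpretable attention transformer
    for 4-class heart-disease classification with attention-based
    saliency, and an adversarially trained convolutional/recurrent
    network with a discriminator for patch wear-position assessment and
    adjustment suggestions. Model cores are implemented in compiled code;
    an end-to-end reporting pipeline ties the modules together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    graphics,
    grDevices,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
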