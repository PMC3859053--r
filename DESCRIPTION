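Package: arhar
Title: Autoregressive Features and Kernel Discriminants for Smartphone Activity Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale implementation of an accelerometer-based human activity
    recognition pipeline. Preprocesses triaxial acceleration recordings
    (exponential low-pass gravity removal, order-3 moving-average smoothing,
    sliding-window segmentation), extracts autoregressive-coefficient features
    via Burg's maximum-entropy method with AIC-based model-order selection and
    SNR-based window-length selection, validates models through residual
    whiteness diagnostics, suppresses phone-position-induced within-class
    variance with radial-basis kernel discriminant analysis, and classifies six
    activities with a small feed-forward neural network. Includes a synthetic
    multi-subject, multi-position signal generator so every stage is testable
    without recorded data, plus a command-line interface for the train /
    evaluate / classify flows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
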