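Package: amfn
Title: Adaptive Multimodal Fusion Networks for Clinical Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts patient outcomes from heterogeneous biomedical time
    series by fusing several physiological modalities (e.g. ECG, blood
    pressure, respiration, labs) into a single representation. Implements an
    adaptive multimodal fusion network built from modality-specific temporal
    encoders, bilinear cross-modal attention, a per-sample modality graph
    refined by graph convolutions, sigmoid modality gating, a contrastive
    alignment penalty, and context-aware query fusion, together with the
    accompanying ICU-style preprocessing pipeline (resampling, overlapping
    windowing, missingness filtering, two-stage imputation, z-scoring) and a
    synthetic multimodal-signal generator with known ground truth so every
    component can be tested without access-controlled clinical data.
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
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
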