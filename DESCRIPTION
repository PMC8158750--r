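Package: bcgvf
Title: Ventricular Fibrillation Detection from Ballistocardiography
Version: 0.1.0
Authors@R: person("BCG-VF", "Developers", email = "bcgvf@example.org",
    role = c("aut", "cre"))
Description: Detects ventricular fibrillation (VF) in single-channel
    ballistocardiography (BCG) recordings sampled at 125 Hz. Implements the
    full analysis pipeline: Daubechies-6 wavelet detail reconstruction and
    least-mean-squares adaptive cancellation of ventilator artifacts,
    segmentation into 7 s windows, autocorrelation enhancement followed by a
    discrete Stockwell (S) transform, a 22-element time-frequency feature
    set, Mann-Whitney U relevance testing with Benjamini-Yekutieli false
    discovery rate control, correlation-based hierarchical feature
    clustering, and classifier evaluation (logistic regression and random
    forest) under intra-subject 10-fold and leave-one-subject-out
    paradigms. Ships a seeded multi-subject synthetic BCG cohort simulator
    (sinus rhythm, fibrillatory oscillation, motion and ventilator
    artifacts) for end-to-end exercise of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    withr,
    digest,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
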