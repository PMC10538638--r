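Package: ctenvr
Title: Cortical Tracking of the Speech Envelope from Continuous EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for estimating cortical tracking of the
    speech envelope (CTenv) from continuous EEG with forward temporal
    response functions (TRFs). Provides EEG preprocessing (resampling,
    windowed-sinc and Butterworth filtering, mastoid re-referencing,
    epoching, amplitude-based artifact rejection, evoked averaging),
    multiband Hilbert envelope extraction from stimulus audio, lagged
    ridge-regression TRF estimation with leave-one-segment-out
    cross-validation, a mismatched-pairing permutation null, and a Bayesian
    association layer (robust observed-versus-null comparison, linear models
    of clinical scores on band-wise CTenv, and hierarchical logistic models
    of trial-level treatment response). A synthetic-data module generates
    envelopes, ground-truth TRF kernels, EEG, cohort tables and trial-level
    records with known structure so that every stage can be validated
    against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
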