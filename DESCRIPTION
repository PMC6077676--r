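Package: pcgclass
Title: Multidomain Feature Extraction and Classification of Heart Sound
    Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying phonocardiogram (PCG) recordings as
    normal or abnormal. Implements the full pipeline: synthetic heart-sound
    generation with ground-truth state boundaries, preprocessing (10 Hz
    high-pass, spike removal, amplitude normalization), four-state
    segmentation (S1, systole, S2, diastole) via a duration-constrained
    Viterbi decoder on the homomorphic envelope, extraction of 515 features
    across nine domains (time intervals, per-state spectra, normalized
    amplitudes, band and state energies, record spectrum, cepstrum,
    cyclostationarity, higher-order statistics, and sample and fuzzy-measure
    entropy), support vector machine models with a radial-basis kernel for
    signal-quality estimation and diagnosis, correlation-based feature
    ranking, and the PhysioNet/CinC 2016 weighted sensitivity-specificity
    scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    graphics,
    jsonlite,
    kernlab,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
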