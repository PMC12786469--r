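Package: eegsonify
Title: Parametric Sonification of EEG Spectral Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for turning multichannel resting-state EEG into sound.
    Sliding-window Welch spectral analysis yields relative band powers
    (delta/theta/alpha/beta/gamma) and normalized spectral entropy,
    aggregated into ten topographic scalp regions; these features drive a
    parameter-mapping synthesiser (sine/triangle oscillators, filtered
    pink/white noise, tremolo, bit-crushing, entropy-controlled resonant
    filtering) rendered offline to 48 kHz mono audio. The package also
    extracts objective acoustic descriptors from rendered sonifications,
    compares groups with Welch t-tests and Benjamini-Hochberg correction,
    and provides the listener-evaluation statistics: exact binomial tests
    against a probability-matching chance level with Holm correction,
    group-level permutation tests, Fleiss' kappa with bootstrap confidence
    intervals, and Monte Carlo power estimation. A seeded synthetic-EEG
    generator makes the full pipeline testable without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, signal, jsonlite, yaml, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
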