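Package: cryspect
Title: Spectrographic and Structural Analysis of Neonatal Cry Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative analysis of newborn cry recordings:
    short-time intensity metering (volume-unit and peak-programme traces on a
    100 ms grid, in 16-bit PCM magnitude units), short-time magnitude spectra,
    autocorrelation fundamental-frequency tracking, silence-based segmentation
    of a cry into a word/sentence/phrase hierarchy, two-cohort descriptive
    statistics with Student/Welch t tests, fixed-length VU/PPM feature vectors
    with ARFF export, and four exemplar/tree classifier families evaluated by
    training-set, stratified 10-fold and 75 percent split protocols. Includes
    a synthetic cry generator that scripts the burst/pause hierarchy and
    renders harmonic-stack audio so the full pipeline is testable without
    clinical recordings, plus an end-to-end study runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    foreign,
    withr,
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
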