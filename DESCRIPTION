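Package: cpascene
Title: Corrected Projections Algorithms for Source Identification in
    Auditory Scenes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies which elements of a large learned dictionary of
    sound spectra are present in an observed superposition (an "auditory
    scene"). Implements the corrected projections estimate, in which each
    dictionary element's contribution to the reconstruction is gated by its
    instantaneous similarity to the observation, both as a batch
    least-squares fit and as a recursive estimator of the
    recursive-least-squares/Kalman family that tracks presence parameters
    together with an uncertainty matrix. Includes synthetic scene and
    click-train generators, template-matching and principal-component
    baselines, a short-time spectrogram front end for audio, a
    decomposition of the estimator's internals into predicted
    cortical-unit activities with adaptation statistics, and a command
    line interface for scripted experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
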