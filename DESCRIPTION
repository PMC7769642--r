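Package: dlksrn
Title: Heart Valve Ailment Detection from Phonocardiograms via Spline-Kernel
    Chirplet Features and a Deep Layer Kernel Sparse Representation Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies phonocardiogram (PCG) recordings as normal or one of
    four heart valve ailments (mitral valve prolapse, aortic stenosis, mitral
    regurgitation, mitral stenosis). Recordings are bandpass filtered and
    amplitude normalized, transformed to the time-frequency domain with a
    spline-kernel Chirplet transform, and summarized per frequency atom by
    L1-norm, sample entropy and permutation entropy into a 1200-dimensional
    feature vector. Classification stacks two extreme-learning-machine
    autoencoders over the features and applies kernel sparse representation
    classification with per-class reconstruction residuals. Includes a
    deterministic five-class synthetic PCG generator, stratified hold-out and
    k-fold evaluation with confusion-matrix metrics, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
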