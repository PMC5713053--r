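Package: mifala
Title: Motor-Imagery EEG Classification with Firefly-Automaton Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A processing chain for four-class motor-imagery electroencephalography
    (EEG): Butterworth band-pass preprocessing and epoching, local
    characteristic-scale decomposition (LCD) of sensorimotor channels into
    intrinsic scale components, one-vs-rest common spatial pattern (CSP)
    filtering over the ISC-augmented channel set, serial fusion of
    frequency-domain and spatial feature blocks, wrapper feature selection by a
    firefly algorithm whose absorption coefficient is adapted per swarm member
    by a linear reward-penalty learning automaton, and classification by
    spectral regression discriminant analysis (SRDA). Includes a synthetic
    motor-imagery generator with class-dependent spatial covariance so the full
    pipeline is exercisable without recorded data, plus stratified
    cross-validation and the usual agreement metrics (accuracy, Cohen's kappa,
    per-class precision/recall/F-measure).
License: MIT
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
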