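Package: surgsound
Title: Acoustic Classification of Electrosurgical Instrument-Tissue
    Interaction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for classifying instrument-tissue interaction from the
    sound of electrosurgery (diathermy). Implements a log-mel-spectrogram
    front end (short-time Fourier transform, triangular mel filterbank,
    decibel scaling, global normalization, fixed-size auditory-image
    rendering), a transfer-learning style classifier (frozen convolutional
    feature extractor plus a softmax head trained with RMSprop and early
    stopping), evaluation utilities (confusion matrices, per-class
    precision/recall/F1, top-1 accuracy, tissue-transition localization in
    audio streams), IIR notch filtering of electrosurgical alarm tones, and
    a fully seeded synthetic surgical-audio generator so the entire
    pipeline can be trained and validated without access to recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    caret
Config/testthat/edition: 3
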