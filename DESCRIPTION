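Package: phonoscreen
Title: Congenital Heart Disease Screening from Phonocardiograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end screening pipeline for congenital heart disease
    from phonocardiogram (PCG) recordings. Implements duration-constrained
    hidden Markov model segmentation of the four heart-sound phases
    (S1, systole, S2, diastole), Mel-frequency spectral coefficient and
    homomorphic-envelope feature maps, energy-gated local-overlay feature
    fusion, and a lightweight convolutional classifier with coordinate
    attention and mixed pooling. Includes a deterministic synthetic PCG
    generator with ECG fiducials so the whole pipeline can be exercised
    and validated without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
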