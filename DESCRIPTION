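Package: mobidecode
Title: Decoding Expressive Movement Qualities from Mobile EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for decoding Laban effort qualities of
    expressive whole-body movement from delta-band scalp EEG recorded
    together with body-worn accelerometry. Provides a synthetic
    mobile-brain/body-imaging session generator, BrainVision/CSV readers,
    delta-band time-lag feature construction, local Fisher discriminant
    analysis (LFDA) for supervised dimensionality reduction, per-class
    Gaussian mixture classifiers with BIC model-order selection,
    random-subsampling cross-validation with forward channel selection,
    motion-artifact quality control (cross-correlation, coherence and
    spectrogram audits), and projection of classifier posteriors into the
    four-axis Laban effort space.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    data.table
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
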