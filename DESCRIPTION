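Package: refluxacc
Title: Accelerometric Gastroesophageal Reflux Scoring and pH-Metry Concordance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-invasive scoring of gastroesophageal reflux (GER) from
    sub-xiphoid accelerometer recordings. Implements the spectral
    quality-control chain (60 Hz band-stop, fixed-segment FFT, spectral
    de-jittering, broadband artifact excision, reconstruction and
    decimation to 60 Hz), resampled-spectrogram mean-amplitude scoring
    with the 1 microvolt positivity rule and episode/pattern features,
    comparator Boix-Ochoa composite pH-metry scoring with acid-episode
    detection, paired 2x2 diagnostic concordance analysis, and a seeded
    synthetic generator of paired accelerometer and pH recordings with
    ground truth. Includes a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
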