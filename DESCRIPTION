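Package: finsong
Title: Detection and Long-Term Trend Analysis of Fin Whale 20 Hz Song
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for the analysis of fin whale (Balaenoptera
    physalus) 20 Hz pulse songs in passive acoustic recordings. Includes a
    synthetic song generator (chirp pulses in brown noise with
    bi-gram-dependent inter-pulse intervals and implanted long-term
    trends), a low-complexity temporal convolutional network for pulse
    detection with a spectrogram template-matching baseline, refined
    spectro-temporal pulse measurement (precise timing, -6 dB bandwidth,
    center frequency and SNR), sequence and bout grouping with quality
    filters, Gaussian-mixture pulse-type classification, and modal-value
    trend regression for inter-annual IPI drift and intra-annual
    center-frequency shifts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mclust,
    jsonlite
Config/testthat/edition: 3
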