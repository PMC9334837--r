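Package: usnoise
Title: Ultrasonic Noise Survey Analysis for Animal Facilities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Calibrated measurement and screening of audible and ultrasonic
    noise in laboratory-animal facilities. Reads 16-bit PCM WAV recordings
    from high-sample-rate microphones, anchors them to absolute sound
    pressure via a 94 dB SPL / 1 kHz reference tone, computes analyser-style
    FFT autospectra in one-second epochs (6400 lines to 100 kHz), integrates
    named frequency bands (delta-cursor readout), applies background-noise
    energy subtraction, builds difference and mitigation-reduction tables,
    detects tonal, impact and frequency-modulated events, and screens
    detections for radio-frequency interference artifacts by cross-device
    comparison. Includes a seeded synthetic acoustic-scene generator so the
    whole pipeline is testable without facility recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
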