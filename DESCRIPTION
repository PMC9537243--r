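Package: dttbp
Title: Continuous Blood Pressure Estimation from Single-Sensor Pulse
    Waveforms via the Diastolic Transit Time
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Beat-to-beat blood pressure estimation from a single
    continuous pulse waveform (capacitive pressure sensor, tonometer or
    photoplethysmogram) using the diastolic transit time, the intra-beat
    interval from systolic peak to diastolic trough.  Provides a seeded
    pulse-waveform simulator with ground-truth hemodynamics, beat
    delineation and intra-beat feature extraction, cuff-anchored
    calibration, empirical baseline-wander modelling and subtraction,
    signal-quality control, comparator methods (zero-phase Chebyshev II
    band-pass, discrete-wavelet-transform detrending and slope transit
    time), beat-to-beat blood pressure variability indices, and
    method-agreement statistics (Pearson, Bland-Altman, AAMI/ISO 81060-2
    bounds, Brown-Forsythe variance comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
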