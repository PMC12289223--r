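Package: ambubrs
Title: Baroreflex Sensitivity from ECG and Pulse Waveforms
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Beat-to-beat baroreflex sensitivity (BRS) analysis for
    multichannel cardiovascular recordings. Detects per-beat fiducial points
    in ECG and pulse waveforms (PPG, arterial line, volume-clamp finger
    pressure), derives beat features (RR, pulse arrival time, pulse
    amplitude, upstroke, rise/decay ratio, systolic pressure), estimates the
    SBP-to-RR transfer function with magnitude-squared coherence in the
    0.04-0.15 Hz band, applies ambulatory signal-qualification criteria, and
    runs interventional-study and 24-hour sliding-window pipelines. Includes
    a synthetic hemodynamics generator with known baroreflex gain for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
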