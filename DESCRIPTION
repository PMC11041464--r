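Package: cohtms
Title: Simulation and Analysis of an EEG Coherence-Gated TMS Trigger System
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale simulator and analysis library for a closed-loop
    transcranial magnetic stimulation (TMS) trigger that fires when the
    beta-band (14-30 Hz) magnitude-squared coherence between two scalp EEG
    channels exceeds an adaptively decaying threshold. Provides streaming
    per-second Welch coherence estimation, baseline calibration of the
    trigger threshold by order statistics, the per-second trigger state
    machine with threshold decay and post-stimulus pause, a random-interval
    control condition, a synthetic two-channel EEG generator with known
    ground-truth coherence and coherence-dependent motor-evoked-potential
    (MEP) amplitudes, and the evaluation statistics (coefficients of
    variation, two-sided variance-ratio tests, paired comparison counts).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
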