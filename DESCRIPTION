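Package: pulsewave
Title: Pulsatile Hemodynamics Analysis of Arterial Pressure and Flow Waveforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for pulsatile arterial hemodynamics: pulse wave
    analysis (landmark detection on ensemble-averaged aortic pressure
    waveforms via higher-order derivative sign logic), wave separation
    analysis (forward/backward pressure decomposition with characteristic
    impedance estimated from the early-systolic pressure-flow slope), wave
    power analysis (dP x dQ with compression/expansion wave classification),
    and pressure-only synthetic flow waveform generation. Includes a
    tube-load paired pressure-flow simulator with exact ground truth and
    heart-failure progression presets, delimited-text waveform I/O, and
    Bland-Altman / Spearman method-agreement statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: signal, stats, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
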