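Package: navload
Title: Cognitive Load and Affective Analysis of Multimodal Assistive-Navigation Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing and analysis of synchronized multimodal physiological
    recordings (16-channel EEG at 512 Hz, electrodermal activity at 16 Hz,
    inter-beat-interval series) acquired while visually impaired users navigate
    with a white cane or a sensory-substitution device. Implements the EEG
    conditioning chain (band-pass, power-line notch, Savitzky-Golay artifact
    suppression, band decomposition, resting-state baseline normalization),
    hemispheric log-power asymmetry statistics for cognitive-load estimation,
    log power-ratio valence state for homologous electrode pairs, electrodermal
    tonic/phasic decomposition with skin-conductance-response detection, RMSSD
    heart-rate variability and its change versus rest, and behavioral
    navigation metrics. Ships a synthetic-trial generator with known ground
    truth (injectable hemispheric power ratios, blink artifacts, SCR events,
    inter-beat jitter, event schedules) so the full pipeline is testable
    without access to recordings, plus HDF5 stream container and
    event-annotation I/O with trial-timeline alignment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    zoo,
    rhdf5,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
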