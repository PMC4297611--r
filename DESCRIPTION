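Package: ichseizr
Title: Seizure Detection and Quantification for Two-Channel Telemetry EEG
    in Rat Models of Intracerebral Hemorrhage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for continuous two-channel (ipsilateral and
    contralateral) telemetry EEG recorded after experimental striatal
    hemorrhagic stroke in rats. Provides baseline-referenced root-mean-square
    amplitude measures, Welch power spectral density with empirical confidence
    intervals, cross-hemispheric magnitude-squared coherence tested against a
    randomized time-shift/time-reversal surrogate null, amplitude-threshold
    interictal spike detection, automated ictal event delimitation with
    laterality classification, per-subject seizure summaries, lesion
    volumetry from serial section areas, peri-event telemetry (temperature
    and activity) deltas, and cohort-level statistics (exact 2x2 contingency
    test and Mann-Whitney U). Includes a synthetic two-channel telemetry-EEG
    generator with exact ground truth (behavioral-state background, ictal
    bursts with postictal suppression, downward interictal spikes,
    controllable cross-channel coupling) so every stage is testable without
    animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
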