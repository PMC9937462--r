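Package: divasim
Title: Speech Motor Control Simulation with Articulatory Feedback Control
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A computational model of speech motor control in the DIVA
    (Directions Into Velocities of Articulators) tradition. Speech targets are
    time-segmented min/max regions in auditory (F0-F3) and somatosensory
    (place, pressure, voicing) space; productions combine a learned
    feedforward motor program with feedback control that maps delayed sensory
    errors through a damped Jacobian pseudoinverse of a static vocal-tract
    forward fit. The package simulates closed-loop productions, learns motor
    programs over repeated iterations, synthesizes audio with a source-filter
    formant synthesizer, extracts pitch and formant targets from sustained
    vowel recordings, and implements validation metrics (normalized RMSE,
    segmental SNR, paired t-tests with pooled-variance Cohen's d).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
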