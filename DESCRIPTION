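Package: reflexfes
Title: Adaptive Reflexive Control of Multichannel Functional Electrical
    Stimulation for Gait Assistance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Hardware-free toolkit for event-triggered functional electrical
    stimulation (FES) walking assistance. Detects gait phases from insole
    pressure and sagittal shank-angle signals with a rule-based finite state
    machine, generates eight-channel stimulation amplitude sequences by
    convolving gait-event impulses with normalized second-order low-pass
    impulse-response envelopes, and adapts stimulation timing (the envelope
    time coefficient) and lateral-gastrocnemius pulse width across gait
    cycles with an iterative learning rule. A synthetic treadmill-gait
    generator with ground-truth labels allows end-to-end closed-loop
    evaluation without any sensor or stimulator hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
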