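Package: q15pipe
Title: Desk-Scale Simulator for Layered Real-Time Biosignal DSP on 8-Bit Microcontrollers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a layered real-time acquisition and digital signal
    processing architecture of the kind used on open-source-hardware
    biomedical sensor platforms built around 8-bit AVR microcontrollers.
    Provides bit-exact Q15 fixed-point arithmetic with saturating
    conversion and round-half-to-even quotients, a virtual multiplexed
    10-bit ADC front end with per-channel bounded FIFO queues, non-blocking
    software timers, rational IIR/FIR filtering, polyphase decimation,
    Goertzel single-bin spectral power estimation, sliding-window
    segmentation with block energy, a deterministic pipeline executive with
    loss accounting, and cycle/memory cost models that predict real-time
    feasibility (maximum filter length, simultaneous Goertzel detector
    count, FFT rate limits) on a 16 MHz, 2 KiB-RAM target. Includes
    synthetic biosignal generators (infrared blink channel with
    powerline-harmonic interference, voice-like audio, two-axis
    accelerometry) and end-to-end scenario runners that compare the
    fixed-point pipeline against a double-precision reference by Pearson
    correlation, plus a System Usability Scale scorer.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
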