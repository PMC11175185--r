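Package: semgfusion
Title: Dual-Stream Convolutional Recurrent Feature Fusion for Surface EMG
    Gesture Recognition
Version: 0.1.0
Authors@R:
    person("semgfusion", "maintainers", email = "maintainers@semgfusion.dev",
           role = c("aut", "cre"))
Description: End-to-end myoelectric gesture recognition from multi-channel
    surface electromyography (sEMG): Butterworth high-pass filtering, Z-score
    normalization, sliding-window segmentation, the five Hudgins time-domain
    features (MAV, ZC, SSC, WL, RMS), and a dual-stream classifier that fuses
    a per-window feature encoder with a per-window raw-signal encoder
    (one-dimensional convolutions with an inner recurrent layer) before a
    two-layer bidirectional LSTM sequence head.  The network, its gradients
    and the Adam optimizer are implemented natively in R so the whole
    pipeline runs without an external deep-learning framework.  A
    class-conditional synthetic sEMG generator emulating NinaPro DB1-style
    recordings (10 channels, 100 Hz, 5-s activations) makes the pipeline
    testable without downloading the benchmark data; a minimal MAT v5 reader
    loads real NinaPro subject files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
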