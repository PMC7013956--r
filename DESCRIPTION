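Package: adaptecg
Title: Perceptually Adaptive Non-Uniform Sampling Codec for Multi-Lead ECG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Encoder and decoder for multi-lead electrocardiograms based on
    perceptually derived medical relevance. A relevance template defined on a
    duration-normalized heartbeat is projected beat-by-beat onto detected wave
    borders (P-onset, P-end, QRS-onset, QRS-end, T-end), drives a pointwise
    local sampling interval that is quantized to a compact shared side channel,
    and yields a non-uniform signal representation; cubic-spline interpolation
    reconstructs the uniform ECG. Includes a parametric synthetic ECG generator
    with ground-truth annotations, a derivative-energy wave delineator, a
    time-varying FIR anti-alias filter bank, a bit-exact binary container for
    the non-uniform stream, and a diagnostic-distortion evaluation suite
    (global and per-wave PRD, peak-to-peak error, compression ratio, weighted
    diagnostic distortion over 18 heartbeat features, Beurling-type sampling
    density).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
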