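Package: adwt
Title: Analog Approximation of the Discrete Wavelet Transform
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs continuous-time analog filter banks (Butterworth high-pass
    details filters and band-stop notch approximation filters) that approximate
    the discrete wavelet transform of Daubechies mother wavelets, with per-level
    cut-off halving in place of decimation. Provides the reference digital DWT
    filter bank, state-space simulation of the analog filters on sampled
    signals, analytic group-delay analysis with fixed-delay equalization,
    side-by-side DWT/ADWT coefficient alignment, EEG band-power epoch features
    with a sleep/wake classifier and leave-one-out cross-validation, and seeded
    generators for ECG-like and two-state EEG-like test signals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    nnet,
    signal,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
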