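Package: wavecg
Title: Wavelet-Based QRS Detection, Delineation and Beat Classification
    for Single-Channel ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing chain for single-channel electrocardiograms built on a
    multilevel discrete wavelet transform with the Daubechies db6 wavelet.
    Denoises recordings by removing the two finest detail bands and the
    coarsest approximation (high-frequency noise and baseline wander),
    detects QRS complexes by amplitude thresholding of the summed D3-D5
    detail components with a physiological refractory period, delineates
    Q, R, S and T fiducial points, extracts an eight-dimensional per-beat
    feature vector (RR interval, Q/R/S/T amplitudes, QRS duration, QT and
    ST intervals), and classifies beats into Normal, LBBB, RBBB and Paced
    classes with a from-scratch backpropagation multilayer perceptron or a
    kernel support vector machine. Includes beat-by-beat evaluation metrics
    (sensitivity, positive predictivity, detection error rate), readers for
    WFDB-style and CSV records and annotations, and a synthetic ECG
    generator with exact ground-truth landmarks for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
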