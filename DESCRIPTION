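Package: ecgpaper
Title: Synthesis and Digitization of Paper-Style ECG Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Round-trip toolkit for electrocardiogram (ECG) paper images.
    Renders multi-lead ECG time-series onto standard ECG paper rasters
    (coarse/fine grid, calibration pulses, printed and handwritten-style
    text) and degrades them with realistic document artifacts: creases,
    image-quilted wrinkle textures, affine/projective viewpoint changes,
    imaging noise and color temperature shifts. The digitization side
    estimates and removes page rotation via the Radon transform, inpaints
    text by a fast-marching first-order scheme, removes the background grid
    with a residual-learning convolutional denoiser (or a classical color
    method), segments lead strips, extracts the trace by connected-component
    analysis and column-wise search, and converts pixels back to calibrated
    millivolt series. Fidelity is quantified with SNR, median-noise SNR,
    MSE and RR-interval error metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    png,
    jsonlite,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
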