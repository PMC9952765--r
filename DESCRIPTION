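Package: csimotion
Title: Quantification of Subtle Hand Motion from WiFi Channel State
    Information
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Signal-processing pipeline that turns WiFi channel state
    information (CSI) into counts, mean frequency and duration of subtle
    hand motion such as resting tremor and finger tapping.  Implements
    amplitude/phase/phase-difference/ratio extraction from complex CSI,
    Z-score normalization, third-order Butterworth bandpass filtering,
    SVD-based principal component selection, short-time energy
    segmentation, Savitzky-Golay smoothing and three-criterion peak
    detection, together with a Fresnel-zone synthetic CSI simulator with
    known ground truth (packet loss and slow-response artifacts included)
    and evaluation utilities (relative-error accuracy, accuracy-versus-
    distance regression, interpolated and symmetry-mapped accuracy
    contours).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
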