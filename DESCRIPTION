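Package: nirsmotion
Title: Motion Artifact Correction for fNIRS Using Thermal Video Optode Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Contactless correction of motion artifacts in functional
    near-infrared spectroscopy (fNIRS) time series. Optode displacement is
    estimated from thermal-infrared video by pyramid-accelerated,
    frequency-domain normalized cross-correlation template tracking restricted
    to Otsu-segmented skin. The displacement signal drives a time-frequency
    exclusion procedure: a generalized Morse continuous wavelet transform of
    the fNIRS signal is masked where the motion scalogram and the Morlet
    wavelet coherence between signal and motion both exceed a threshold, and
    the corrected signal is recovered by inverse transform. Includes a
    synthetic-data generator (thermal video, resting-state fNIRS,
    motion-coupled artifacts, hemodynamic-response block activations),
    reference correction methods (wavelet-IQR, PCA, spline/MARA, CBSI), and a
    GLM-based simulation benchmark scoring signal-to-noise ratio and mean
    squared error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
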