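Package: tempotools
Title: Dual-Channel Optical Voltage-Imaging Signal Processing
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for dual-channel optical voltage recordings in
    which a genetically encoded voltage indicator (GEVI) channel is paired with
    a voltage-insensitive reference channel. Implements frequency-dependent
    convolutional (Wiener) unmixing of heartbeat and hemodynamic artifacts from
    the voltage channel, photobleach detrending, notch and zero-phase band
    filtering, channel decrosstalking, SVD low-rank movie denoising, coherence
    and wavelet spectrograms, phase-amplitude cross-frequency coupling,
    sharp-wave ripple detection, traveling-wave velocimetry, and a penalized
    regression model decomposing apparent inter-channel delays into
    indicator-kinetic and physiological components. Ships a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    MASS,
    jsonlite,
    yaml,
    rhdf5
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
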