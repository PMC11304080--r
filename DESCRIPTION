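Package: pillartrack
Title: Pillar Deflection Tracking and Contractility Analysis for Cardiac
    Microbundles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated analysis of brightfield time-lapse movies of beating
    cardiac microbundles suspended between two elastomeric pillars.
    Segments the pillar regions by local Otsu thresholding, tracks
    Shi-Tomasi fiducial markers inside each pillar mask with a pyramidal
    Lucas-Kanade sparse optical flow tracker, identifies valley (fully
    relaxed) frames, splits the recording into beats with optional drift
    correction, and converts pillar deflections into twitch forces and
    tissue stresses through linear cantilever beam mechanics. Includes a
    synthetic two-pillar movie generator with exact ground-truth motion
    for end-to-end validation, plus single-movie and batch drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    pracma,
    grDevices,
    graphics,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
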