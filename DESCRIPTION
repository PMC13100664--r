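Package: orbitstack
Title: Camera-Orbit Planning, Focus-Stack Acquisition and Scaled Measurement for Macro Photogrammetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hardware-free toolkit for specimen-stationary macro photogrammetry
    rigs. Plans camera-orbit viewpoint sequences in six machine axes (X/Y/Z
    translation, azimuth/elevation rotation, and a dedicated focus-stacking
    axis), acquires per-viewpoint focus stacks from a thin-lens digital-twin
    camera (or a directory of pre-captured frames) using an edge-based
    sharpness criterion with hysteresis thresholds, fuses stacks into extended
    depth-of-field images with per-pixel depth-index maps, and applies
    two-landmark scale constraints to reconstructed models for 1D morphometric
    measurement with standard error statistics (MAPE, MAE, RMSE).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
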