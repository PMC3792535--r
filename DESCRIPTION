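Package: tlcseg
Title: Automatic Lane Segmentation in Thin-Layer Chromatography Images
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects sample lanes in digitised thin-layer chromatography
    (TLC) plates without requiring the number of lanes or a regular lane
    spacing. The plate image is projected to a one-dimensional intensity
    profile, smoothed by reconstructing a Morlet continuous wavelet
    transform over an adaptively selected scale band, and segmented in
    three phases: candidate detection via h-maxima/h-minima morphological
    transforms, removal of false lanes by adaptive statistical rules, and
    recovery of subtle low-contrast lanes from the profile derivative.
    Includes a synthetic plate generator with ground truth for validation
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
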