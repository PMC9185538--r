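Package: radenh
Title: Radiographic Image Enhancement with Nonsubsampled Shearlet Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multiscale enhancement of low-contrast radiographic (X-ray)
    images. Images are decomposed with an undecimated (nonsubsampled)
    shearlet transform into one low-frequency approximation band and
    per-level directional detail bands; the approximation band is contrast
    corrected with adaptive gamma correction driven by a weighted intensity
    histogram, the detail bands are denoised and sharpened with
    gradient-domain guided filtering plus detail boosting, and the image is
    reconstructed by the inverse transform. Includes the four no-reference
    quality metrics commonly used to score such enhancement (average
    gradient, information entropy, spatial frequency, edge intensity), a
    deterministic phantom generator for synthetic X-ray-like test images,
    parameter-sweep harnesses, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
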