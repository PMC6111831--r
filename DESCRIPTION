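Package: hiercontour
Title: Hierarchical Bio-Inspired Contour Detection with Surround Modulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hierarchical model of early biological vision for detecting
    salient contours in colour images. The cascade mimics the retina/LGN
    (single-opponent, spatially low-pass colour channels), V1 (oriented
    derivative-of-Gaussian double-opponent filter bank with MAX pooling and
    self-normalisation), and V2 (orientation-elongated elliptical pooling with
    one-shot feedback), followed by non-classical receptive field surround
    inhibition whose strength is modulated by local luminance, contrast, and
    colour-orientation differences, combined across two spatial scales.
    Includes a deterministic synthetic stimulus generator (gratings, textured
    squares, isoluminant colour edges, cluttered scenes) with exact boundary
    ground truth, post-processing (non-maxima suppression, hysteresis
    thresholding), and distance-tolerant precision-recall evaluation of
    boundary maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    stats,
    tools,
    utils,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
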