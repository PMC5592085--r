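Package: odcircle
Title: Contrast-Based Circular Optic Disc Localization and Segmentation
    in Retinal Fundus Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Localizes and segments the optic disc in colour retinal
    fundus photographs with a circular model fitted by maximal
    ring contrast. Localization combines morphological top-hat vessel
    enhancement of the complemented green channel, a vessel-density map,
    a Hough-line vessel-convergence map, and a brightness detector built
    from circular and rectangular averaging filters; segmentation scans
    concentric rings around the estimated center and fits a flexible
    four-sector circle. Includes the standard evaluation measures
    (normalized center error, Jaccard, Dice, mean average boundary
    distance) and a seedable synthetic fundus generator with exact
    ground truth for end-to-end testing without external image data.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
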