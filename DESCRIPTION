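Package: bmsradar
Title: Optimization-Based Radar Image Reconstruction for Breast Microwave
    Sensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Radar-based image reconstruction for breast microwave sensing
    (BMS) from monostatic frequency-domain S11 measurements. Implements the
    delay-and-sum (DAS) and delay-multiply-and-sum (DMAS) beamformers and an
    optimization-based radar reconstruction (ORR) that minimizes a complex
    least-squares data-fit loss over reflectivity profiles by gradient
    descent under a Born-style linear forward scattering model, with an
    optional second-order scattering forward model. Includes image-quality
    metrics (signal-to-clutter ratio, localization error), rule-based tumour
    detection with sensitivity/specificity and ROC evaluation, and a
    synthetic monostatic scan simulator emulating circular-arc scan
    protocols with layered phantoms and reference scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
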