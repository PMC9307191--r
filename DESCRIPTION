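Package: leafgreen
Title: Pixel-Weighted Leaf Greenness Analysis from Palette-Quantized Canopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies crop health from canopy photographs by coarse palette
    quantization of RGB images, classification of green palette codes,
    pixel-weighted color statistics (R, G, B, R/G, B/G) with percentile
    bootstrap confidence intervals for treatment contrasts, a dark-to-light
    green area ratio analysed with a random-intercept mixed model on the log
    scale, and an ordinary least-squares regression of fruit yield on the
    early-season ratio. Includes a seeded synthetic-trial generator that
    emulates a small replicated field experiment so the whole pipeline is
    testable without field photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    emmeans,
    png,
    stats,
    tools,
    utils,
    withr
Suggests:
    EBImage,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
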