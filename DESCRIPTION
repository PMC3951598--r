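Package: bakevision
Title: Multispectral Quality Assessment of Baked Goods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to assess surface browning and water content of baked
    goods (butter cookies) from visible/near-infrared multispectral image
    cubes. Implements a sensory-anchored browning score built by Fisher
    discriminant analysis over pooled cookie-surface pixels, a quadratic
    response surface of browning over baking time and oven temperature, and
    a NIPALS partial least squares regression predictor of average water
    content from mean reflectance spectra, with pixel-wise browning and
    water maps. Includes a calibrated synthetic multispectral image
    generator emulating a two-set baking experiment (fixed-temperature time
    series and a full time-by-temperature grid), adaptive-threshold surface
    segmentation, TIFF/CSV/JSON input and output, and a reproducible
    end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    MASS,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
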