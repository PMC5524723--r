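Package: msrbeta
Title: Adaptive Greyscale Image Enhancement via Multi-Scale Retinex and
    an Incomplete-Beta Transform
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Adaptive contrast enhancement for low-contrast, unevenly
    illuminated greyscale images such as near-infrared frames from
    recirculating aquaculture fish tanks. Images are first corrected for
    uneven illumination with the Multi-Scale Retinex algorithm in the
    logarithm domain, then passed through a normalized incomplete-Beta
    greyscale transform whose two shape parameters are selected
    automatically by particle swarm optimization against a grey-value
    variance (contrast) fitness. Includes the associated image-quality
    metric suite (contrast, MSE, PSNR, Shannon entropy), linear-stretch
    and histogram-equalization baselines, a seeded synthetic scene
    generator emulating tank imaging conditions, and PNG/BMP/TIFF
    greyscale image input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    tiff,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
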