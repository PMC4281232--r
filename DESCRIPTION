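Package: carapacer
Title: Calibrated Multispectral Colour and Pattern Phenotyping for Shore Crabs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify animal coloration and pattern from calibrated
    multispectral (LW/MW/SW/UV) images: grey-standard linearization and
    reflectance equalization, tetrahedral colour-space saturation and hue
    ratios, a Fourier band-pass granularity (pattern energy) spectrum,
    phenotypic diversity in a multidimensional phenotype space with
    sample-size-controlled resampling, and the downstream statistics
    (jackknifed discriminant classification, Spearman size correlations,
    Box-Cox transformed fixed-effects models with stepwise interaction
    removal). Includes seed-deterministic synthetic image and cohort
    generators with ground-truth records, and a reproducible pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    MASS,
    car,
    tiff,
    yaml,
    jsonlite,
    readr,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    broom,
    knitr,
    rmarkdown
Config/testthat/edition: 3
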