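Package: ftirfuse
Title: Multi-Block Chemometric Analysis of FTIR Microbial Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for whole-cell FTIR metabolic fingerprinting of microbial
    isolates grown under crossed nutrient and temperature conditions. Provides
    spectral quality screening, region-wise Savitzky-Golay second
    differentiation and extended multiplicative signal correction (EMSC),
    replicate averaging and media-aligned multi-block assembly, consensus
    (multi-block) PCA with block scores, super weights and block-score
    projection, genus-wise correlation-loading analysis with
    second-derivative peak picking, a streak-plate growth-score model, and a
    synthetic FTIR study generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
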