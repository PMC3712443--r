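Package: floralsignals
Title: Floral Signal Convergence Analysis for Bee-Pollinated Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify convergence of floral colour and shape signals
    in plant communities as perceived by hymenopteran pollinators. Converts
    floral reflectance spectra into loci in the hexagon model of trichromatic
    bee colour vision, tests whether focal species occupy distinct regions of
    colour space via a bootstrap distinctness statistic, performs open-curve
    eigenshape morphometrics of floral outlines (tangent-angle shape functions,
    singular value decomposition, canonical variates discrimination), and maps
    binary floral-colour characters onto phylogenies with Fitch-Hartigan
    parsimony to count independent evolutionary origins. Includes synthetic
    data generators with known ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
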