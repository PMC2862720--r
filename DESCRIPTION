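Package: ihcquant
Title: Quantitative Segmentation and Concordance Analysis for Multiplexed
    Immunohistochemistry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying chromogenic immunohistochemistry (IHC)
    micrographs and for validating a multiplexed microchannel staining
    platform against conventional whole-section scoring. Pixels are
    classified into stained cells, counterstained cells and background with
    Gaussian mixture colour models fitted by expectation-maximization and
    combined by Bayes' rule; expression is summarised as the product of the
    stained-area ratio and the mean stain intensity. Includes translation of
    Allred, HER2 and Ki-67 scores to a common four-level ordinal scale,
    inter-method agreement statistics (Kendall's W with its chi-square test,
    Cohen's and Fleiss' kappa, exact binomial concordance intervals, Levene
    and t tests, Latin-square reproducibility designs), a synthetic
    micrograph and paired-ratings generator with exact ground truth, and a
    finite-difference advection-diffusion simulator of antibody binding to a
    reactive tissue wall in a microchannel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    grDevices,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    car
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    e1071,
    mclust,
    vegan
Config/testthat/edition: 3
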