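Package: oilblendr
Title: Fatty-Acid Blend Analytics, Nutritional Indices, Relaxometry and
    Thermal-Degradation Statistics for Edible Oil Blends
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for designing and characterising edible oil blends from
    their fatty-acid composition. Validates and mixes fatty-acid profiles,
    solves binary blend recipes for a target omega-6/omega-3 ratio, and
    computes the standard nutritional quality indices (PUFA/SFA, index of
    atherogenicity, index of thrombogenicity, hypocholesterolemic/
    hypercholesterolemic ratio) together with the calculated iodine value.
    Also fits mono-exponential low-field NMR relaxation curves
    (inversion-recovery T1, CPMG T2), inverts the T1/T2 ratio to a mean
    rotational correlation time via Bloembergen-Purcell-Pound spectral
    densities, detects the oxidation induction time in isothermal DSC
    traces by the tangent method, and provides the statistics used in
    frying-oil degradation studies: summary-statistic one-way ANOVA with
    Tukey HSD compact letter displays, and standardised PCA. Seeded
    synthetic-data generators make every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
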