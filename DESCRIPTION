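Package: seroscreen
Title: Autoantigen Discovery Screens and Serological Microarray Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for serological autoantibody discovery studies that pair
    immunoprecipitation mass spectrometry (IP-MS) antigen screens with custom
    antigen microarray validation. Implements identification-level filtering of
    label-free protein quantification tables (quality flags, replicate
    presence, negative/mock-control exclusion) and iBAQ relative-abundance
    summaries; Perseus-style differential screening with Gaussian down-shift
    imputation, permutation-based FDR t-tests, z-score hierarchical clustering
    and PCA; the antigen-microarray pre-processing chain (background
    subtraction, negative-control correction, triplicate averaging, IgG
    median-centring, winsorize-to-missing, missingness filtering, KNN
    imputation); tie-corrected Mann-Whitney U, Spearman and Kruskal-Wallis
    validation statistics; and random-forest case/control classification with
    confusion metrics. Simulators for both data types with known ground truth
    support end-to-end testing and power evaluation.
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
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
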