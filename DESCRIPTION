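Package: musclemap
Title: MRI-Based Abdominal Skeletal Muscle Quantification from Proton-Density
    Fat-Fraction Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies abdominal skeletal muscle on axial L3-level
    proton-density fat-fraction (PDFF) maps: total and fat-free muscle
    cross-sectional area via an intensity threshold separating intramyocellular
    from extramyocellular fat, height-normalized abdominal muscle mass indices,
    and mean-PDFF myosteatosis. Includes the Janssen bioelectrical-impedance
    skeletal-muscle-mass equation, a seeded Gaussian-copula generator for
    synthetic cohorts and synthetic PDFF slices with compartment masks, and the
    cohort-level statistical machinery (Welch t and chi-square group
    comparisons, Pearson correlation, standardized age- and sex-adjusted linear
    regression, obesity stratification) needed for MRI-vs-BIA concordance
    analyses.
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
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    digest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
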