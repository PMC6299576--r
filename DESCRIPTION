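Package: lungdens
Title: Automated Density-Based CT Scoring of Lung Structural Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies structural lung disease on chest CT by density
    histogram analysis. Reads CT volumes (NIfTI or DICOM series) in
    Hounsfield units, isolates the lungs with a rule-based segmentation,
    computes density-histogram characteristics (mean lung density, mode,
    standard deviation, skewness, kurtosis), and scores the burden of
    high-attenuating abnormalities as the percentage of lung at or above
    fixed or histogram-adapted thresholds such as MLD + 1 SD. Includes
    regional (upper/lower) scoring, a cohort-level statistical battery
    (Spearman correlation with interpretation bands, paired Wilcoxon,
    intraclass correlation, Bland-Altman agreement), and a synthetic
    chest-CT phantom generator with ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
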