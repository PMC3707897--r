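Package: cdbold
Title: Cortical Decorrelation Analysis of Center-Surround BOLD Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing contextual (center-surround) modulation in
    visual-cortex BOLD activation patterns under the cortical decorrelation (CD)
    model. Computes the per-voxel measured modulation index d_M, the closed-form
    fully-decorrelating coefficient d_T, and their relation to the Pearson
    correlation between center and surround activation patterns; compares the CD
    prediction against slope-one linear, free linear, and cubic alternatives with
    orthogonal-distance goodness of fit, leave-one-out cross-validation and AIC,
    and against MAX and AVERAGE response-combination rules; quantifies retinotopic
    BOLD spread via eccentricity profiles, polynomial zero crossings and the
    Schwartz log cortical-magnification mapping; and provides the nonparametric
    statistics used throughout (sign test, Mann-Whitney U, Kolmogorov-Smirnov,
    Friedman). A synthetic multi-subject voxel-data generator with controllable
    retinotopic, correlational and interaction structure makes every stage
    testable without imaging data.
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
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
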