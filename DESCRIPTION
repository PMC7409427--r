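Package: octacvd
Title: Deep Choroidal Vasculature Visualization and Vascular Density from
    Swept-Source OCT Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating deep choroidal vasculature on swept-source
    optical coherence tomography angiography (SS-OCTA). Builds Bruch-membrane
    referenced single-pixel en-face slab pairs on the device axial grid,
    binarizes them with Otsu's method, scores OCTA against en-face OCT by
    pixel agreement with four-colour comparison maps, selects an optimal
    imaging depth, measures choroidal vascular density (CVD), applies
    artefact and image-quality exclusions, and provides the cohort statistics
    (Pearson correlation, multivariable regression with per-100-micron SCT
    slopes, one-way ANOVA from raw or summary data, covariate-adjusted
    ANCOVA, Lilliefors normality). Includes a synthetic choroid phantom
    generator with known vessel ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    png,
    yaml,
    nortest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
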