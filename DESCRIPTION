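Package: bodymapr
Title: Pixel-Wise Statistical Body Maps and Avatar-Based Body Perception Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for quantifying body image perception from two complementary
    assessments: 2-D body concern outlines drawn on a standard manikin, and 3-D
    avatar body-part sliders paired with tape measurements. Builds proportional
    body maps (fraction of participants marking each pixel) and Gaussian-smoothed
    two-proportion z maps with permutation-based, cluster-extent-corrected
    inference; calibrates avatar sliders to centimeters by piecewise linear
    interpolation and computes perceived-minus-actual discrepancy scores; and
    reproduces the usual cohort summary statistics (Welch t from summary data,
    chi-square tests, frequency tallies, Benjamini-Hochberg adjustment, MANCOVA
    with Wilks' lambda and post hoc ANCOVA). Includes a fully synthetic cohort
    generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
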