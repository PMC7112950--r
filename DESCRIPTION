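Package: cartsynth
Title: Sequential CART Synthesis of Tabular Data with Utility Assessment and Disclosure Control
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Generates synthetic versions of rectangular datasets by sequential
    classification-and-regression-tree (CART) conditional synthesis with leaf
    donor sampling, assesses their general utility (aligned marginal and
    bivariate frequency comparisons with total-variation distances) and
    specific utility (standardized coefficient differences, confidence
    interval overlap, and a lack-of-fit chi-square test against models fitted
    to the original data), and applies statistical disclosure control
    (exact-replicate detection and removal, FAKE_DATA provenance labeling,
    level collapsing and top-coding). Includes a simulator for a
    heart-rate-variability study design (four physiological variables, a
    medium HRV-fitness correlation, configurable skew, outliers and
    missingness) and a grid runner for robustness studies across sample size,
    skew and missingness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, MASS, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
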