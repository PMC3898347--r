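Package: myopiaGxE
Title: Gene-Education Interaction Analysis for Refractive Error and Myopia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how educational attainment modifies the effect
    of common genetic variants on refractive error. Implements weighted
    polygenic risk scores from allele dosages, spherical-equivalent refraction
    phenotyping with standard clinical category cut-points, covariate-adjusted
    linear and logistic association models, education-stratified slopes with a
    homogeneity F test, joint genetic-risk-by-education strata odds ratios, and
    additive-interaction measures (Rothman's synergy index, RERI, attributable
    proportion) with delta-method confidence intervals. A synthetic-cohort
    generator reproduces the statistical structure of a population-based
    myopia cohort so the whole pipeline is testable without access to
    individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    optparse,
    withr
Config/testthat/edition: 3
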