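Package: freevitd
Title: Free 25-Hydroxyvitamin D Estimating Equations and Internal Validation Tools
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calculators for free 25-hydroxyvitamin D from routinely and
    non-routinely available serum biomarkers, including three linear estimating
    equations (with vitamin D binding protein concentration and Gc-diplotype
    offsets) and the single-site binding-equilibrium equation of Bikle. Also
    provides the machinery used to develop and internally validate such
    equations: development/validation cohort splitting, log-transformed
    least-squares regression, forward selection under an adjusted R-squared
    improvement rule with pairwise interaction search, Bland-Altman bias and
    95% limits of agreement, P15/P30 accuracy proportions, and RMSE. A
    synthetic cohort generator calibrated to published marginal distributions
    of community-dwelling older adults lets the full develop-validate loop run
    without access to the source data.
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
    optparse
Config/testthat/edition: 3
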