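Package: chiromet
Title: Chemometric Chirality Sensing from Induced CD/UV Spectra
Version: 0.1.0
Authors@R: person("Chiromet", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates induced circular dichroism (CD) and UV absorption
    spectra of multicomponent chiral amine and amino-alcohol mixtures
    derivatized by an achiral chromophoric probe, and recovers each
    enantiomer's concentration (hence total concentration, enantiomeric
    ratio and absolute configuration) by multivariate and multiblock
    calibration: principal component regression, NIPALS PLS2, consensus
    multiblock PCA/PLS, and LASSO-assisted variants, with leave-one-out
    cross-validation for model selection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
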