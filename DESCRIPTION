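Package: arealgp
Title: Model-Based Geostatistics for Spatially Misaligned Areal Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Joint geostatistical modelling of a bivariate areal outcome
    (life expectancy at birth for two population groups, observed over one
    partition of a study region) and an areal covariate (a deprivation
    index observed over a different, possibly non-nested partition). Both
    sets of areal values are treated as averages of a single spatially
    continuous Gaussian process, so that their variances and
    cross-covariances are double integrals of an exponential kernel over
    polygon pairs, approximated by regular-grid quadrature. The package
    provides maximum-likelihood estimation via the exact Gaussian
    likelihood, spatially continuous prediction with non-exceedance
    probability maps, variogram-based model validation with Monte-Carlo
    tolerance envelopes, and a simulation framework for misaligned
    tessellations, parameter-recovery and coverage studies. The Chiang
    abridged life-table estimator of life expectancy at birth is included
    as a utility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    rlang,
    stats,
    tibble,
    utils,
    grDevices,
    withr,
    yaml
Suggests:
    mvtnorm,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
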