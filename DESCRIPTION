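Package: migvar
Title: Variance Decomposition and Batch-Effect Removal for Multi-Site
    Cell-Migration Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying and correcting sources of variability in
    high-content live-cell migration imaging performed across laboratories.
    Extracts per-cell morphology and protrusion/retraction dynamics from
    labeled mask movies, applies trajectory quality control, smoothing,
    instantaneous-speed and principal-component preprocessing, decomposes
    feature variance into nested biological and technical components with a
    maximum-likelihood linear mixed-effects model (random intercepts for
    laboratory, person, experiment, technical replicate and cell),
    quantifies cumulative variability across design levels, removes batch
    effects by subtracting predicted technical random intercepts, and
    quantifies 3D spheroid invasion distances against a four-point
    reference sphere.  A synthetic-data generator emulating a multi-site
    study design with known ground truth supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    Matrix,
    tiff,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    lme4,
    ggplot2,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
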