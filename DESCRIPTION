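Package: paleocolr
Title: Colour Inference from Fossil Melanosome Morphometrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing plumage colour from melanosome
    length and diameter measurements. Implements per-sample morphometric
    feature vectors, two-dimensional kernel-density morphospaces with a
    proportional-overlap statistic, highest-density-region identification of
    platelet-shaped nanostructures with a Gaussian-mixture fallback,
    backward-stepwise quadratic discriminant colour classification with
    self-test and leave-one-out validation, taphonomic shrinkage sensitivity
    analysis, Mantel tests of anatomical autocorrelation, rarefaction of
    variance, and a bivariate-lognormal synthetic-data generator for
    extant training libraries and fossil slabs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    mclust,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
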