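Package: circART
Title: Angular Randomisation Test and Comparators for Two-Sample Circular Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-sample hypothesis tests for circular (angular) data, centred on
    the Angular Randomisation Test (ART), whose statistic sums the geodesic
    angular distances between every cross-sample pair of points and whose
    significance is assessed by permutation. Also provides five comparator
    tests (Watson's U2 in asymptotic and permutation versions, the
    Watson-Wheeler uniform-scores test in asymptotic and permutation versions,
    and a Rao spacing-frequencies permutation test), exact samplers for the von
    Mises, axial von Mises and wrapped skew-normal families, and a Monte-Carlo
    framework for estimating type-I error rates and power over scenario grids.
    A command-line interface exposes single-test runs on angle files and full
    simulation grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
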