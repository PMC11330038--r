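Package: abquant
Title: Quantification of Amyloid-Beta Deposits in Whole-Slide Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying amyloid-beta deposit
    burden on digitized immunohistochemistry slides. Implements Reinhard
    stain normalization in log-opponent (l-alpha-beta) color space,
    resolution harmonization, uniform tiling, sliding-window patch
    classification into per-class confidence heatmaps, gray-/white-matter
    region mapping, thresholding and connected-component blob counting,
    per-square-micron density tables, overlay rendering, and the
    accompanying nonparametric cohort statistics (Kruskal-Wallis with
    Dunn-Bonferroni post-hoc, Wilcoxon rank-sum, chi-square/Fisher,
    one-way ANOVA). Ships a synthetic-slide generator with exact ground
    truth and deterministic oracle classifiers so the full pipeline can be
    validated against known deposit placements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    png,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
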