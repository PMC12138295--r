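Package: heteropower
Title: Sampling Designs and Statistical Power for Heterogeneous
    Wearable Heart-Rate Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying how controlling
    interindividual and intraindividual variability changes the number of
    weekend/weekday sample pairs needed to detect a nightly heart-rate
    difference, and the effect size at the point of significance.  Provides
    a calibrated synthetic-cohort generator for nightly sleep heart rate
    (between-individual baseline spread, small within-individual nightly
    noise, seasonal drift, heterogeneous weekend effects, missingness),
    nonparametric primitives (Cliff's delta, exact and tie-corrected
    Mann-Whitney U and Wilcoxon signed-rank tests, Kruskal-Wallis with Dunn
    post hoc), the sequential significance-onset statistic, four cohort-wide
    and three within-individual resampling designs, descriptive variability
    analyses, and a Monte-Carlo power analysis over Cliff's delta grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
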