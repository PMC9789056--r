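Package: gutdrift
Title: Time-Scale Analysis of Longitudinal Gut Microbiota Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how human gut microbial communities change
    over months to years of repeated sampling. Detects short-term blooms of
    individual taxa against each subject's own average, organises pairwise
    Bray-Curtis dissimilarities into sampling-interval groups, tests for a
    rise in dissimilarity with interval using a Wilcoxon rank-sum statistic
    referred to a permuted-time-point null (pairwise dissimilarities are not
    independent, so ordinary critical values do not apply), estimates the
    proportion of a later sample's community attributable to an earlier
    sample with a Bayesian microbial source-tracking Gibbs sampler, performs
    principal coordinates analysis, and screens external factors with Mantel
    tests. A seeded generator of synthetic longitudinal compositional
    cohorts makes every stage testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml,
    vegan,
    Biostrings,
    biomformat,
    Rcpp
LinkingTo: Rcpp
Suggests:
    ape,
    withr,
    jsonlite,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
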