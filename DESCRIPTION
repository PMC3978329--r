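Package: rvgeom
Title: Geometric Rare-Variant Association Tests Under Genotype Misclassification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Gene-based rare-variant association testing with the geometric
    family of length (burden-style) and joint (variance-component-style)
    statistics built from L^p norms of case and control minor-allele frequency
    vectors, together with tools to quantify how allele-level genotype
    misclassification affects them. Provides an error model for
    major-to-minor (eps01) and minor-to-major (eps10) allele flips in both
    differential and non-differential regimes, a Hardy-Weinberg case-control
    cohort simulator with relative-risk-driven case frequencies, phenotype
    permutation inference, empirical power and type-I-error estimation over
    simulation grids, meta-regression summaries of grid results, and
    closed-form asymptotic power, sample-size and type-I-inflation
    calculators for the L1 and scaled J2 statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
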