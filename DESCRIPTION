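Package: pcgp
Title: Principal Component Regression and GREML for Across-Population
    Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genomic prediction of breeding values across weakly
    related populations. Implements SNP quality control (call rate,
    per-population minor allele frequency, Hardy-Weinberg chi-square),
    pedigree (A) and VanRaden genomic (G) relationship matrices with
    Yang-style blending, principal component regression on SNP genotypes
    with eigenvalue- or sum-of-squares-based component ranking, a
    semi-supervised variant that extracts components from reference and
    test genotypes jointly, cross-validation (5-fold random or
    population-stratified) selection of the number of components by
    minimum mean squared error, single-random-effect GREML via
    eigendecomposition and profiled restricted likelihood, best-case
    accuracy scans over model size, and a multi-population
    Balding-Nichols/gene-dropping simulator that generates pedigrees,
    genotypes and additive phenotypes with realistic population structure.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
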