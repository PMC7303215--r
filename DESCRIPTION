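Package: sexdiffwes
Title: Sex-Stratified Genetic Architecture Analysis of Whole-Exome Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing the genetic architecture of a complex
    trait between women and men within a cohort, using whole-exome
    variant data. Implements a qualitative single-variant screen
    (Fisher exact allele/dominant/recessive tests and the
    Cochran-Armitage trend test, with an empirical significance
    threshold derived from control cohorts), a quantitative
    annotation-category burden analysis with a sex-label permutation
    null, EM haplotype frequency estimation with pairwise linkage
    disequilibrium, LD clumping and polygenic risk scoring, and
    clinical severity comparisons between variant carriers and
    non-carriers. A seeded synthetic-cohort generator reproduces the
    data structure these analyses assume so that every stage can be
    exercised end to end without access to protected genotypes.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
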