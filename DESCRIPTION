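Package: sgsr
Title: Fine-Scale Spatial Genetic Structure Analysis for Codominant Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate spatial autocorrelation analysis of codominant
    multilocus genotypes (Smouse-Peakall r) with permutation null envelopes,
    bootstrap error bars and the multiclass omega criterion; non-parametric
    correlogram heterogeneity tests (per-class t-squared and whole-correlogram
    omega) between groups of individuals; Loiselle kinship coefficients with
    within- and between-generation distance profiles; per-group genetic
    diversity summaries; and a spatially explicit forward simulator of seed
    dispersal around adults (Mendelian dioecious mating, dispersal kernels,
    optional Janzen-Connell distance-dependent thinning) that generates the
    genotype-plus-coordinates tables the analyses consume. All user-facing
    functions take plain data frames and return tibbles.
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
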