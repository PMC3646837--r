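# sgsr — fine-scale spatial genetic structure for codominant markers

`sgsr` is an R package for quantifying and testing **fine-scale spatial
genetic structure (SGS)** in continuously distributed plant populations
genotyped at codominant multiallelic loci (microsatellites) and mapped with
planar coordinates. It is aimed at population geneticists and ecologists who
ask how relatedness decays with distance, how that decay changes across
ontogenetic stages (seedlings → saplings → adults), and whether it differs
between habitats such as soil strata.

The core statistic is the multivariate spatial autocorrelation coefficient
*r* for a geographic distance class *h*,

    r_h = ( Σ_{i≠j} x_ij(h) c_ij ) / ( Σ_i w_i(h) c_ii ),

computed from the Gower-centered matrix of squared genetic distances
`c = -½ (I - 11'/n) D² (I - 11'/n)`, where the per-locus squared distance is
half the squared Euclidean distance between allele-dosage vectors (the
codominant 0/1/2/3/4 table), `x_ij(h)` indicates membership of pair (i, j)
in class *h*, and `w_i(h)` counts how often individual *i* is paired in the
class. Under no structure `E[r] = -1/(N-1)`. Inference is by permutation of
genotypes among sampling locations (null envelopes and two-sided p-values),
pair bootstrap (error bars), and Fisher's multiclass criterion
`ω = -2 Σ ln p_k` for "no autocorrelation at any distance". Companion tools
provide:

* **Correlogram heterogeneity tests** between two groups — per-class
  `t²_k = [(r_Ak − μ_Ak) − (r_Bk − μ_Bk)]² / (V_Ak + V_Bk)` with a
  sample-size bias correction from the pooled-label permutation null, and a
  whole-correlogram ω test; the permutation unit can be individuals or
  whole plots (the calibrated choice for plot-level groupings such as
  soil class).
* **Loiselle kinship coefficients** `F_ij` with the small-sample term, and
  within- versus between-generation kinship-by-distance profiles
  (relatedness `r = 2 F_ij`).
* **Genetic diversity summaries** per group (Na, Ne, private alleles, Ho,
  He, F with across-locus standard errors).
* A **spatially explicit forward simulator**: dioecious Mendelian mating,
  Gaussian/exponential seed-dispersal kernels, optional Janzen–Connell
  distance-dependent thinning, multi-plot landscapes with soil strata — the
  generative model the statistics are validated against.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()`,
`glance()` and `autoplot()` methods on every result.

## Worked example

Simulate a study-scale landscape (14 transect plots of 250 m, ~380
individuals in four size classes, 7 microsatellite-like loci, seed dispersal
σ = 10 m) and build the first-year-seedling correlogram at 50 m distance
classes with 999 permutations and bootstraps:

```r
library(sgsr)
library(dplyr)

sim   <- simulate_population(sim_config(), seed = 42)
first <- filter(sim$data, size_class == "FIRST_YEAR")
cg    <- spatial_autocorrelation(first, edges = seq(50, 250, 50),
                                 n_perm = 999, n_boot = 999, seed = 1)
tidy(cg)
#> # A tibble: 5 × 10
#>   class_lo class_hi midpoint n_pairs      r perm_lo perm_hi boot_lo boot_hi     p
#>      <dbl>    <dbl>    <dbl>   <int>  <dbl>   <dbl>   <dbl>   <dbl>   <dbl> <dbl>
#> 1        0       50       25     415 0.326  -0.0259  0.0137  0.301    0.348 0.001
#> 2       50      100       75     134 0.0810 -0.0411  0.0277  0.0430   0.120 0.001
#> 3      100      150      125      46 0.0725 -0.0665  0.0503  0.0136   0.141 0.013
#> 4      150      200      175      25 0.0799 -0.0851  0.0700 -0.0204   0.182 0.029
#> 5      200      250      225      10 0.241  -0.148   0.117   0.126    0.343 0.001
glance(cg)
#> # A tibble: 1 × 7
#>   omega p_omega p_omega_chisq n_perm n_boot     n  seed
#> 1  57.2   0.001  0.0000000122    999    999   140     1
```

Read: 415 first-year pairs lie within 50 m of each other and are strongly
more related than random (`r = 0.33`, far above the 97.5% null envelope
0.014); autocorrelation stays positive but weakens with distance, and the
multiclass ω = 57.2 (p = 0.001) rejects "no SGS at any distance" — the
signature of limited seed dispersal the simulator was configured to
produce. `autoplot(cg)` draws the correlogram with error bars and envelope.
From the same dataset, `diversity_summary()`, `kinship_correlogram()`,
`correlogram_heterogeneity()` and the one-call `run_study()` produce the
remaining tables (diversity, within/between-generation kinship profiles,
size-class and soil heterogeneity tests), and `write_study_bundle()` writes
them as self-describing TSV files.

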