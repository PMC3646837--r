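---
title: "Fine-scale spatial genetic structure with sgsr: models, tests and the simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fine-scale spatial genetic structure with sgsr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`sgsr` analyses fine-scale spatial genetic structure (SGS) in continuous
plant populations genotyped at codominant multiallelic markers
(microsatellites) and mapped with planar coordinates. Positive SGS — nearby
individuals being more related than random pairs — arises mainly from
limited seed dispersal, and is subsequently reshaped by mortality during
recruitment (for instance distance-dependent Janzen–Connell thinning near
maternal trees) and by environmental filtering. The package quantifies SGS
per distance class, tests it by permutation, compares it between groups of
individuals (ontogenetic stages, soil strata), and ships a forward simulator
that generates data under exactly the processes the analyses are meant to
detect.

```{r, message = FALSE}
library(sgsr)
library(dplyr)
```

## The multivariate autocorrelation statistic

The genetic distance between two diploid individuals is built per locus from
allele-dosage vectors $y_i$ (entries 0/1/2 summing to 2):
$d^2_{ij,l} = \tfrac12\lVert y_{il} - y_{jl}\rVert^2$, which yields the
familiar codominant table — identical genotypes 0, $AA{:}AB$ 1, $AB{:}AC$ 1,
$AB{:}CD$ 2, $AA{:}BC$ 3, $AA{:}BB$ 4. Loci missing in either member of a
pair are dropped and the summed distance is rescaled by
$L_\text{total}/L_\text{complete}$, keeping its expectation unbiased under
missingness at random. Half-called genotypes are treated as fully missing,
because dosage vectors must sum to 2.

The squared-distance matrix $D$ is Gower-centered,
$c_{ij} = -\tfrac12\,(d^2_{ij} - \bar d^2_{i\cdot} - \bar d^2_{\cdot j} +
\bar d^2_{\cdot\cdot})$, so that every row sums to zero and the diagonal
carries each individual's variance contribution. For geographic distance
class $h$ with indicator $x_{ij}(h)$ the autocorrelation is

$$r_h \;=\; \frac{\sum_{i\ne j} x_{ij}(h)\, c_{ij}}
                {\sum_i w_i(h)\, c_{ii}},
\qquad w_i(h) = \sum_{j \ne i} x_{ij}(h),$$

a Moran-type coefficient that weights each individual by how often it is
paired within the class. Two algebraic facts anchor the implementation and
its tests: if a single class contains *all* pairs, $r = -1/(N-1)$ exactly
(the row-sum-zero identity), and a lone pair gives $r = -1$. The expected
value under no structure is therefore slightly negative, not zero, and
shrinks with sample size — which is exactly why the heterogeneity test below
needs a bias correction.

Distance classes are defined by upper edges $e_1 < \dots < e_K$ with class 1
the closed interval $[0, e_1]$ and class $k>1$ equal to $(e_{k-1}, e_k]$;
pairs beyond $e_K$ are excluded. Co-located pairs land in class 1, and
printed intervals like 0–50, 51–100 m reproduce exactly. In a multi-plot
design with plots much farther apart than $e_K$, cross-plot pairs drop out
automatically.

## Inference: permutations, bootstraps, and the $\omega$ criterion

The null hypothesis — genotypes distributed at random over the sampling
locations — is simulated by globally permuting the genotype-to-location
assignment (999 times by default, the conventional protocol at this study
scale). Permutation is not stratified by plot: distance classes at or below
the plot length already confine all comparisons to within plots. Each class
gets a 95% null envelope (2.5% and 97.5% quantiles) and a two-sided
permutation p-value with add-one smoothing,
$p_h = \bigl(1 + \#\{|r^*_h - \bar r^*_h| \ge |r_h - \bar
r^*_h|\}\bigr)/(1 + n_\text{perm})$, centred on the null mean so the
negative null expectation does not masquerade as signal. Both conventions
(envelope exceedance and the p-value) are reported because practitioners
read both.

Bootstrap error bars resample each class's pair list with replacement and
recompute $r$ from the resampled numerator and denominator contributions; a
class needs at least two pairs, otherwise the interval is blank.

"SGS somewhere along the correlogram" is tested with Fisher's combination
$\omega = -2\sum_k \ln p_k$ over the defined classes. Its p-value uses a
permutational reference: each permutation replicate's $r$ vector is scored
against the whole replicate set to produce a pseudo-p vector and a null
$\omega^*$; the upper-tail $\chi^2_{2K}$ approximation is reported alongside
(`p_omega_chisq`). The permutational version is the default because the
per-class p-values are discrete and dependent, which the $\chi^2$ reference
ignores.

All randomised routines take one integer `seed` and consume a single
sequential RNG stream (no parallelism anywhere in the package), so every
result is byte-reproducible from its seed, and a study bundle records the
derived stage seeds in each table's metadata.

```{r}
sim <- simulate_population(sim_config(), seed = 42)
first <- filter(sim$data, size_class == "FIRST_YEAR")
cg <- spatial_autocorrelation(first, edges = seq(50, 250, 50),
                              n_perm = 199, n_boot = 199, seed = 1)
tidy(cg)
glance(cg)
```

## Comparing correlograms: the $t^2$ and $\omega$ heterogeneity tests

To ask whether two groups (size classes; soil strata) share one SGS pattern,
group labels are permuted among the pooled individuals — locations and
genotypes stay fixed, group sizes are preserved — so the pooled correlogram
is the null reference frame. Writing $\mu_{gk}$ and $V_{gk}$ for the mean
and variance of group $g$'s class-$k$ $r$ across label permutations, the
per-class statistic is

$$t^2_k = \frac{\bigl[(r_{Ak} - \mu_{Ak}) - (r_{Bk} - \mu_{Bk})\bigr]^2}
               {V_{Ak} + V_{Bk}}.$$

Centering each group's $r$ on its own permutation-null mean is the
sample-size-weighted bias correction: the null expectation of $r$ is about
$-1/(N_g-1)$, so unequal groups carry unequal finite-sample biases that
would otherwise be mistaken for heterogeneity. Consequently $t^2$ is
invariant to any bias shared by both groups. When the groups happen to have
equal sizes the two null sets estimate the same bias and are pooled, which
makes "identical groups give $t^2 = 0$" hold exactly. One pass of label
permutations supplies the bias terms, the variances, the per-class p-values
(upper tail of the null $t^2$), and the whole-correlogram
$\omega = -2\sum\ln p_k$ with its permutational p-value — no nested
permutation is needed. The replicate partitions are drawn canonically (the
smaller group always fills from the head of each permutation), so swapping
the group labels reproduces the identical test.

The permutation unit matters. For groupings interleaved *within* plots
(size classes), individuals are exchangeable under the null and
`permute_by = "individual"` (the default) is correct. When the grouping is
a plot attribute (soil class: every individual of a plot carries the same
label), individuals are *not* exchangeable — within-plot pairs share
families, so shuffling individuals underestimates the null variance of the
group correlograms and inflates $t^2$; in our calibration experiments the
individual-level shuffle rejected a true null about four times too often.
`permute_by = "plot"` reassigns whole plots to groups (preserving the plot
count per group) and restores nominal size; it is the choice the soil
comparison uses throughout this package.

The exact statistic behind published GenAlEx-style tables is not printed in
most papers; the definitions above are therefore declared in every output
header, and numerical comparisons with other software should be read as
dialect-sensitive for the permutation-based quantities.

## Kinship profiles within and between generations

The Loiselle kinship coefficient for a pair, relative to reference allele
frequencies $p_{la}$ estimated from $n_l$ gene copies, is

$$F_{ij} = \frac{\sum_l \sum_a (q_{ila}-p_{la})(q_{jla}-p_{la})
  + \sum_l \sum_a p_{la}(1-p_{la})/(n_l-1)}
  {\sum_l \sum_a p_{la}(1-p_{la})},$$

with $q_{ila} \in \{0, \tfrac12, 1\}$ the dosage fractions; loci missing in
either individual are dropped from all sums for that pair. The second
numerator term is the standard small-sample correction. Reported relatedness
is $r = 2F_{ij}$, exact for non-inbred pairs; parent–offspring pairs expect
$F_{ij} = 0.25$. The default reference pools *all* sampled individuals, so
within-generation (seedling–seedling) and between-generation
(seedling–adult) distance profiles are computed on a common footing; a
cohort-specific reference can be supplied explicitly. If the
within-generation curve sits above the between-generation curve at short
distance, the seedlings share parents that were not sampled — adults outside
the frame dominate the local seed rain.

```{r}
ref <- allele_frequencies(sim$data)
kw <- kinship_correlogram(sim$data, seq(50, 250, 50), mode = "within",
                          focal_class = "FIRST_YEAR", reference = ref)
kb <- kinship_correlogram(sim$data, seq(50, 250, 50), mode = "between",
                          focal_class = "FIRST_YEAR", reference = ref)
tibble(class_hi = kw$class_hi, within = kw$fij, between = kb$fij)
```

## The simulator: what it emulates, and what it does not

`sim_config()` defaults encode the sampling design the analyses were built
around: 14 transect plots of 250 m × 40 m spaced 1 km apart, 4 adults per
plot plus seedling cohorts of 10/9/4 per plot (~380 individuals in four
ontogenetic classes), 7 loci with 4–12 alleles each (mean 7.7, Dirichlet(1)
frequencies, allele codes styled as fragment sizes), two soil strata split
at 15% clay using the per-plot clay percentages of a real Amazonian plot
network, and a Gaussian dispersal kernel with $\sigma = 10$ m — seed shadows
concentrated near the maternal crown, the regime that produces clear
positive SGS inside the first 50 m class. Mating is dioecious: sexes are
Bernoulli(½) per adult, redrawn until a plot with offspring has both sexes
(a plot that cannot mate would otherwise abort whole-landscape replicates
at these small per-plot adult counts); each offspring draws its mother and
father uniformly within the plot and inherits one allele per parent per
locus. Janzen–Connell thinning, when enabled, removes each offspring with
probability $\exp(-d/\lambda_{JC})$ at distance $d$ from its mother, by
rejection; $\lambda_{JC}$ may differ per cohort, which is how an older
cohort "remembers" more thinning than a younger one. `sigma` may be
overridden per soil stratum to create the sandy-versus-clay contrasts the
heterogeneity test is aimed at. Setting `sigma = Inf` places offspring
uniformly in the plot; combined with a single plot this is the panmictic
null used for calibration — note that with *several* plots, per-plot
parentage alone creates genuine plot-scale structure even under uniform
placement, so multi-plot landscapes are never a null.

Real data differ from this generator in ways the tests cannot vouch for:
null alleles and scoring error (absent here), uneven adult fecundity and
reproductive asynchrony, pollen flow between plots, multi-generation
pedigree depth, seed dormancy, and environmental filtering acting on
genotypes rather than on dispersal scale. Passing the calibration and power
experiments shows the statistics behave correctly under the stated
processes, not that any particular field dataset satisfies them.

## Numerical and design choices

* **Missing data**: allele code 0 or blank means missing; a half-called
  genotype is fully missing at that locus.
* **Soil tie-break**: exactly 15% clay classifies as `SANDY`; the defining
  phrases ("less than 15%", "greater than 15%") leave the boundary open, so
  the choice is declared here and in `classify_soil()`.
* **Size classes**: heights are banded as $[0,20]$, $(20,40]$, $(40,100]$,
  $(100,200]$ (excluded — too rare to analyse) and $>200$ cm; adults
  recorded without height enter through an explicit `size_class` column.
* **Plot inclusion**: pairwise statistics need pairs, so plots enter the
  analysis only with at least two individuals in some size class
  (`filter_analysis_plots()`), applied before every stage of `run_study()`.
* **Degenerate inputs**: identical genotypes everywhere stop with a
  "no genetic variance" error; a pair sharing no complete locus names both
  individuals; empty distance classes yield blank rows, never dropped rows.
* **Problem sizes in the test-suite experiments** (chosen to estimate rates
  with adequate Monte-Carlo resolution at desk scale): 200 replicates for
  the type-I calibration (n = 120, 199 permutations each), 50 replicates
  per dispersal-grid cell, 100 replicates for each heterogeneity size and
  power experiment (99 label permutations each, ~150 seedlings per
  stratum). Analysis functions themselves default to 999 permutations and
  999 bootstraps — the conventional reporting protocol; the smaller
  replicate-level counts only set the resolution of rate estimates, not of
  any reported analysis.

## Limitations

The permutational $\omega$ reference treats replicate pseudo-p vectors
symmetrically but shares one replicate set between the observed and null
scores; with 999 permutations the induced bias is below the Monte-Carlo
noise. The heterogeneity test's plot-level permutation needs several plots
per group to resolve small p-values (with 7 plots per group there are 3432
distinct assignments); with very few plots the individual-level shuffle is
the only option and its inflation caveat applies. Coordinates are planar
metres; `lonlat_to_planar()` is adequate for a few kilometres only. The
package does not estimate dispersal kernels, Sp statistics, Moran's I, or
parentage; it quantifies and compares distance-class relatedness profiles.
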