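test_that("Loiselle Fij matches hand evaluation for identical homozygotes", {
  # two AA individuals, reference p(A) = p(B) = 0.5 from a large pool:
  # numerator ~ (0.25 + 0.25), denominator 0.5 -> Fij -> 1 as n_l -> Inf
  d <- toy_dataset(list(L1 = rbind(c(1, 1), c(1, 1))), x = c(0, 1), y = 0)
  ref <- tibble::tibble(locus = "L1", allele = c(1, 2), freq = 0.5, n_copies = 1e9)
  f <- loiselle_fij(d, ref)
  expect_equal(f[1, 2], 1, tolerance = 1e-6)
  expect_equal(f[1, 2], oracle_fij_pair(d, 1, 2, ref), tolerance = 1e-12)
})

test_that("Fij matches the brute-force summation to 1e-10 on random datasets", {
  set.seed(41)
  for (rep in 1:3) {
    d <- random_dataset(10, n_loci = 3, n_alleles = 4)
    d$L1.a1[4] <- NA; d$L1.a2[4] <- NA  # missing data path
    ref <- allele_frequencies(d)
    f <- loiselle_fij(d, ref)
    for (i in 1:5) for (j in (i + 1):6) {
      expect_equal(f[i, j], oracle_fij_pair(d, i, j, ref), tolerance = 1e-10)
    }
  }
})

test_that("sample-referenced mean Fij over all pairs is a small negative constant", {
  set.seed(42)
  d <- random_dataset(12, n_loci = 4, n_alleles = 5)
  f <- loiselle_fij(d)
  vals <- f[upper.tri(f)]
  ref <- allele_frequencies(d)
  idx <- which(upper.tri(f), arr.ind = TRUE)
  brute <- vapply(seq_len(nrow(idx)), function(k) {
    oracle_fij_pair(d, idx[k, 1], idx[k, 2], ref)
  }, numeric(1))
  expect_equal(mean(vals), mean(brute), tolerance = 1e-10)
  # self-referenced kinship averages to ~ -1/(2(n-1)) plus the small-sample
  # term ~ +1/(2n-1): a constant of magnitude << diag kinship
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("Fij is symmetric and invariant to allele relabeling, locus order and locus duplication", {
  set.seed(43)
  d <- random_dataset(8, n_loci = 2, n_alleles = 4)
  f <- loiselle_fij(d)
  expect_equal(f, t(f))
  relab <- d
  for (col in grep("\\.a[12]$", names(d), value = TRUE)) {
    relab[[col]] <- relab[[col]] * 11L + 5L
  }
  expect_equal(unname(loiselle_fij(relab)), unname(f), tolerance = 1e-12)
  # duplicating every locus leaves Fij unchanged (numerator and denominator double)
  dup <- d
  dup$L1b.a1 <- d$L1.a1; dup$L1b.a2 <- d$L1.a2
  dup$L2b.a1 <- d$L2.a1; dup$L2b.a2 <- d$L2.a2
  class(dup) <- class(d)
  expect_equal(unname(loiselle_fij(dup)), unname(f), tolerance = 1e-12)
})

test_that("monomorphic-only reference is an error", {
  d <- toy_dataset(list(L1 = rbind(c(1, 1), c(1, 1), c(1, 1))), x = 1:3, y = 0)
  expect_error(loiselle_fij(d), "monomorphic")
})

test_that("parent-offspring pairs average Fij near 0.25 under the generator reference", {
  cfg <- sim_config(n_plots = 1, plot_width = 100, n_adults = 40,
                    cohort_sizes = c(FIRST_YEAR = 100, YOUNG = 0, SAPLING = 0),
                    n_loci = 40, n_alleles = 6, sigma = 20)
  sim <- simulate_population(cfg, seed = 44)
  ref <- dplyr::mutate(sim$truth$freqs, n_copies = 1e9)
  f <- loiselle_fij(sim$data, ref)
  ped <- sim$truth$pedigree
  po <- vapply(seq_len(nrow(ped)), function(k) {
    f[match(ped$id[k], sim$data$id), match(ped$mother[k], sim$data$id)]
  }, numeric(1))
  se <- sd(po) / sqrt(length(po))
  expect_lt(abs(mean(po) - 0.25), 4 * se + 0.01)
})

test_that("within mode with two class members gives that pair's Fij", {
  loci <- list(L1 = rbind(c(1, 2), c(1, 1), c(3, 3), c(2, 3)))
  d <- toy_dataset(loci, x = c(0, 10, 0, 5), y = 0,
                   size_class = c("FIRST_YEAR", "FIRST_YEAR", "ADULT_JUVENILE", "ADULT_JUVENILE"))
  f <- loiselle_fij(d)
  kc <- kinship_correlogram(d, edges = c(50, 100), mode = "within",
                            focal_class = "FIRST_YEAR")
  expect_equal(kc$n_pairs, c(1L, 0L))
  expect_equal(kc$fij[1], f[1, 2])
  expect_equal(kc$r[1], 2 * f[1, 2])
  expect_true(is.na(kc$fij[2]))
})

test_that("mode all is the pair-count-weighted combination of within and between modes", {
  set.seed(45)
  d <- random_dataset(14, n_loci = 3, n_alleles = 5, box = 90)
  d$size_class <- factor(rep(c("FIRST_YEAR", "ADULT_JUVENILE"), 7),
                         levels = levels(d$size_class))
  edges <- c(30, 60, 130)
  ref <- allele_frequencies(d)
  kall <- kinship_correlogram(d, edges, mode = "all", reference = ref)
  kw1 <- kinship_correlogram(d, edges, mode = "within", focal_class = "FIRST_YEAR", reference = ref)
  kw2 <- kinship_correlogram(d, edges, mode = "within", focal_class = "ADULT_JUVENILE", reference = ref)
  kb <- kinship_correlogram(d, edges, mode = "between", focal_class = "FIRST_YEAR", reference = ref)
  for (k in seq_along(edges)) {
    n <- c(kw1$n_pairs[k], kw2$n_pairs[k], kb$n_pairs[k])
    fij <- c(kw1$fij[k], kw2$fij[k], kb$fij[k])
    expect_equal(kall$n_pairs[k], sum(n))
    if (sum(n) > 0) {
      expect_equal(kall$fij[k], sum(n * fij, na.rm = TRUE) / sum(n), tolerance = 1e-12)
    }
  }
})

test_that("r column is exactly twice Fij everywhere", {
  set.seed(46)
  d <- random_dataset(10, n_loci = 2, n_alleles = 4, box = 50)
  d$size_class <- factor(rep("FIRST_YEAR", 10), levels = levels(d$size_class))
  kc <- kinship_correlogram(d, c(25, 75), mode = "all")
  expect_identical(kc$r, 2 * kc$fij)
})
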