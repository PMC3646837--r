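test_that("per-locus squared distance reproduces the codominant distance table", {
  pairs <- list(
    list(c(1, 1), c(1, 1), 0),  # AA vs AA
    list(c(1, 2), c(1, 2), 0),  # AB vs AB
    list(c(1, 1), c(1, 2), 1),  # AA vs AB
    list(c(1, 2), c(1, 3), 1),  # AB vs AC
    list(c(1, 2), c(3, 4), 2),  # AB vs CD
    list(c(1, 1), c(2, 3), 3),  # AA vs BC
    list(c(1, 1), c(2, 2), 4)   # AA vs BB
  )
  for (p in pairs) {
    d <- toy_dataset(list(L1 = rbind(p[[1]], p[[2]])), x = c(0, 1), y = 0)
    D <- genetic_distance(d)
    expect_equal(D[1, 2], p[[3]], info = paste(p[[1]], collapse = "/"))
    expect_equal(D[1, 2], oracle_d2_locus(p[[1]], p[[2]]))
  }
})

test_that("missing-locus rescale: summed d2 scaled by total/complete loci", {
  loci <- list(L1 = rbind(c(1, 1), c(2, 2)),   # d2 = 4
               L2 = rbind(c(NA, NA), c(5, 5))) # missing in individual 1
  d <- toy_dataset(loci, x = c(0, 1), y = 0)
  D <- genetic_distance(d)
  expect_equal(D[1, 2], 8)  # 4 * (2 loci / 1 complete)
  expect_equal(attr(D, "complete_loci")[1, 2], 1L)
})

test_that("pairs sharing no complete locus raise an error naming both individuals", {
  loci <- list(L1 = rbind(c(1, 1), c(NA, NA)),
               L2 = rbind(c(NA, NA), c(2, 2)))
  d <- toy_dataset(loci, x = c(0, 1), y = 0)
  expect_error(genetic_distance(d), "i1.*i2")
})

test_that("genetic_distance + gower_center agree with brute-force oracles", {
  set.seed(31)
  for (rep in 1:5) {
    d <- random_dataset(7, n_loci = 3, n_alleles = 4)
    # inject some missingness
    d$L2.a1[2] <- NA; d$L2.a2[2] <- NA
    D <- genetic_distance(d)
    expect_equal(D, oracle_distance_matrix(d), tolerance = 1e-12, ignore_attr = TRUE)
    C <- gower_center(D)
    expect_equal(C, oracle_gower(unname(D)), tolerance = 1e-12, ignore_attr = TRUE)
    expect_true(all(abs(rowSums(C)) < 1e-9 * max(abs(C), 1)))
    expect_gte(sum(diag(C)), 0)
  }
})

test_that("distance classes follow the [0,e1], (e_{k-1},e_k] convention", {
  edges <- c(50, 100, 150, 200, 250)
  expect_equal(distance_class(0, edges), 1L)
  expect_equal(distance_class(50, edges), 1L)
  expect_equal(distance_class(50.0001, edges), 2L)
  expect_equal(distance_class(250, edges), 5L)
  expect_true(is.na(distance_class(250.1, edges)))
  # 5-point grid spaced 60 m: all 10 pair distances enumerated by hand
  x <- seq(0, 240, 60)
  d <- as.vector(dist(x))
  expect_equal(tabulate(distance_class(d, edges), 5), c(0, 4, 3, 2, 1))
})

test_that("r over a single class holding all pairs equals -1/(N-1)", {
  set.seed(32)
  for (n in 3:10) {
    d <- random_dataset(n, n_loci = 2, n_alleles = 5, box = 10)
    cg <- point_correlogram(d, edges = 1000)
    expect_equal(cg$r[1], -1 / (n - 1), tolerance = 1e-9)
  }
  # N = 2: the single pair gives r = -1
  d2 <- random_dataset(2, n_loci = 2, n_alleles = 5, box = 10)
  expect_equal(point_correlogram(d2, edges = 1000)$r[1], -1, tolerance = 1e-12)
})

test_that("co-located clones drive class-1 r positive", {
  set.seed(33)
  clone <- c(1, 1)
  loci <- list(L1 = rbind(clone, clone, clone, c(2, 3), c(4, 5), c(6, 7)),
               L2 = rbind(clone, clone, clone, c(2, 3), c(4, 5), c(6, 7)))
  d <- toy_dataset(loci, x = c(0, 1, 2, 200, 201, 202), y = 0)
  cg <- point_correlogram(d, edges = c(50, 250))
  expect_gt(cg$r[1], 0)
})

test_that("identical genotypes everywhere raise a no-variance error", {
  loci <- list(L1 = rbind(c(1, 1), c(1, 1), c(1, 1)))
  d <- toy_dataset(loci, x = 1:3, y = 0)
  expect_error(spatial_autocorrelation(d, 10, n_perm = 0, n_boot = 0),
               "no genetic variance")
})

test_that("r is invariant to allele relabeling and locus order", {
  set.seed(34)
  d <- random_dataset(15, n_loci = 3, n_alleles = 4, box = 80)
  edges <- c(30, 60, 120)
  r0 <- point_correlogram(d, edges)$r
  # relabel alleles with an arbitrary injective map
  relab <- d
  for (col in grep("\\.a[12]$", names(d), value = TRUE)) {
    relab[[col]] <- relab[[col]] * 7L + 3L
  }
  expect_equal(point_correlogram(relab, edges)$r, r0)
  # permute locus column blocks
  perm_cols <- c("id", "plot", "x", "y", "height_cm", "clay_pct", "size_class",
                 "soil_class", "L3.a1", "L3.a2", "L1.a1", "L1.a2", "L2.a1", "L2.a2")
  shuf <- d[, perm_cols]
  class(shuf) <- class(d)
  expect_equal(point_correlogram(shuf, edges)$r, r0)
})

test_that("permuting genotypes among locations equals permuting locations", {
  set.seed(35)
  d <- random_dataset(12, n_loci = 2, n_alleles = 4, box = 60)
  edges <- c(20, 40, 80)
  s <- sample.int(12)
  sinv <- integer(12); sinv[s] <- seq_len(12)
  geno_perm <- d
  for (col in grep("\\.a[12]$", names(d), value = TRUE)) {
    geno_perm[[col]] <- d[[col]][s]
  }
  loc_perm <- d
  loc_perm$x <- d$x[sinv]; loc_perm$y <- d$y[sinv]
  expect_equal(sort(point_correlogram(geno_perm, edges)$r),
               sort(point_correlogram(loc_perm, edges)$r))
})

test_that("permutation and bootstrap output is reproducible for a fixed seed", {
  set.seed(36)
  d <- random_dataset(20, n_loci = 3, n_alleles = 4, box = 100)
  a <- spatial_autocorrelation(d, c(30, 60, 120), n_perm = 59, n_boot = 59, seed = 9)
  b <- spatial_autocorrelation(d, c(30, 60, 120), n_perm = 59, n_boot = 59, seed = 9)
  expect_identical(a, b)
  c_ <- spatial_autocorrelation(d, c(30, 60, 120), n_perm = 59, n_boot = 59, seed = 10)
  expect_false(identical(a$perm_lo, c_$perm_lo))
})

test_that("bootstrap interval is blank for classes with fewer than 2 pairs", {
  set.seed(37)
  d <- random_dataset(4, n_loci = 2, n_alleles = 4, box = 1)
  # distances: 10, 100, 90, 301, 291, 201 -> classes 1, 2, 2, 3, 3, 3
  d$x <- c(0, 10, 100, 301); d$y <- 0
  cg <- spatial_autocorrelation(d, c(50, 120, 400), n_perm = 0, n_boot = 29, seed = 2)
  expect_equal(cg$n_pairs, c(1L, 2L, 3L))
  expect_true(is.na(cg$boot_lo[1]) && is.na(cg$boot_hi[1]))
  expect_false(is.na(cg$boot_lo[2]))
})

test_that("bootstrap interval width shrinks roughly like 1/sqrt(n_pairs)", {
  widths <- vapply(c(30, 300), function(n) {
    set.seed(n)
    d <- random_dataset(n, n_loci = 4, n_alleles = 6, box = 10)
    cg <- spatial_autocorrelation(d, edges = 100, n_perm = 0, n_boot = 199, seed = 4)
    cg$boot_hi[1] - cg$boot_lo[1]
  }, numeric(1))
  # pair count grows ~100x between the two sizes; width should drop clearly
  expect_lt(widths[2], widths[1] / 3)
})

test_that("omega is the Fisher combination of the per-class p-values", {
  expect_equal(-2 * (log(0.05) + log(0.05)), 11.98, tolerance = 1e-3)
  set.seed(38)
  d <- random_dataset(25, n_loci = 3, n_alleles = 5, box = 100)
  cg <- spatial_autocorrelation(d, c(30, 60, 120), n_perm = 99, n_boot = 0, seed = 6)
  defined <- !is.na(cg$p)
  expect_equal(sgs_meta(cg)$omega, -2 * sum(log(cg$p[defined])), tolerance = 1e-12)
  expect_equal(sgs_meta(cg)$p_omega_chisq,
               pchisq(sgs_meta(cg)$omega, 2 * sum(defined), lower.tail = FALSE))
  # all p = 1 would give omega = 0 by the same closed form
  expect_equal(-2 * sum(log(c(1, 1, 1))), 0)
})
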