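test_that("offspring alleles always come from the recorded parents", {
  cfg <- sim_config(n_plots = 2, n_adults = 4,
                    cohort_sizes = c(FIRST_YEAR = 6, YOUNG = 4, SAPLING = 3),
                    n_loci = 5)
  sim <- simulate_population(cfg, seed = 61)
  d <- sim$data
  ped <- sim$truth$pedigree
  loci <- sgs_loci(d)
  for (k in seq_len(nrow(ped))) {
    o <- match(ped$id[k], d$id)
    m <- match(ped$mother[k], d$id)
    f <- match(ped$father[k], d$id)
    for (l in loci) {
      a1 <- d[[paste0(l, ".a1")]]; a2 <- d[[paste0(l, ".a2")]]
      expect_true(a1[o] %in% c(a1[m], a2[m]))  # maternal allele
      expect_true(a2[o] %in% c(a1[f], a2[f]))  # paternal allele
    }
  }
  # dioecious: mother and father are distinct individuals of opposite sex
  sx <- sim$truth$sexes
  expect_true(all(sx$sex[match(ped$mother, sx$id)] == "F"))
  expect_true(all(sx$sex[match(ped$father, sx$id)] == "M"))
})

test_that("a fixed seed reproduces the dataset exactly", {
  cfg <- sim_config(n_plots = 2, n_adults = 4,
                    cohort_sizes = c(FIRST_YEAR = 5, YOUNG = 3, SAPLING = 2))
  a <- simulate_population(cfg, seed = 62)
  b <- simulate_population(cfg, seed = 62)
  expect_identical(a$data, b$data)
  expect_identical(a$truth$pedigree, b$truth$pedigree)
  c_ <- simulate_population(cfg, seed = 63)
  expect_false(identical(a$data$x, c_$data$x))
})

test_that("vanishing dispersal co-locates offspring with mothers and drives class-1 r up", {
  cfg <- sim_config(n_plots = 4, n_adults = 6, sigma = 1e-6,
                    cohort_sizes = c(FIRST_YEAR = 15, YOUNG = 0, SAPLING = 0))
  sim <- simulate_population(cfg, seed = 64)
  expect_lt(max(sim$truth$pedigree$dist_to_mother), 1e-4)
  first <- dplyr::filter(sim$data, size_class == "FIRST_YEAR")
  cg <- point_correlogram(first, seq(50, 250, 50))
  expect_gt(cg$r[1], 0.1)
})

test_that("infinite dispersal places offspring uniformly and flattens the correlogram", {
  # single plot: with several plots, per-plot parentage itself creates real
  # plot-scale structure even under uniform placement
  cfg <- sim_config(n_plots = 1, n_adults = 24, sigma = Inf,
                    cohort_sizes = c(FIRST_YEAR = 100, YOUNG = 0, SAPLING = 0))
  sim <- simulate_population(cfg, seed = 65)
  first <- dplyr::filter(sim$data, size_class == "FIRST_YEAR")
  # offspring stay inside their plot's rectangle
  expect_true(all(first$y >= 0 & first$y <= cfg$plot_length))
  cg <- spatial_autocorrelation(first, seq(50, 250, 50), n_perm = 99, n_boot = 0, seed = 66)
  expect_true(cg$r[1] <= cg$perm_hi[1])
})

test_that("impossible configurations error", {
  expect_error(sim_config(sigma = -1))
  expect_error(
    simulate_population(sim_config(n_plots = 1, n_adults = 1,
                                   cohort_sizes = c(FIRST_YEAR = 2, YOUNG = 0, SAPLING = 0)),
                        seed = 1),
    "dioecious"
  )
  # JC thinning that rejects essentially every offspring aborts with an error
  cfg <- sim_config(n_plots = 1, n_adults = 4, sigma = 1e-6, jc = TRUE,
                    lambda_jc = 1e9,
                    cohort_sizes = c(FIRST_YEAR = 2, YOUNG = 0, SAPLING = 0))
  expect_error(simulate_population(cfg, seed = 2), "thinning")
})

test_that("realized allele frequencies converge to generator frequencies", {
  cfg <- sim_config(n_plots = 1, n_adults = 1000, n_loci = 2, n_alleles = c(4, 8),
                    cohort_sizes = c(FIRST_YEAR = 0, YOUNG = 0, SAPLING = 0))
  sim <- simulate_population(cfg, seed = 67)
  est <- allele_frequencies(sim$data)
  joined <- dplyr::inner_join(est, sim$truth$freqs, by = c("locus", "allele"),
                              suffix = c("_est", "_true"))
  se <- sqrt(joined$freq_true * (1 - joined$freq_true) / joined$n_copies)
  expect_true(all(abs(joined$freq_est - joined$freq_true) <= 3.5 * pmax(se, 1e-6)))
})

test_that("soil-stratum overrides steer the dispersal scale per plot", {
  cfg <- sim_config(n_plots = 2, n_adults = 6, clay_pct = c(5, 75),
                    sigma_by_soil = c(SANDY = 100, CLAY = 1),
                    cohort_sizes = c(FIRST_YEAR = 30, YOUNG = 0, SAPLING = 0))
  sim <- simulate_population(cfg, seed = 68)
  ped <- sim$truth$pedigree
  d_sandy <- ped$dist_to_mother[ped$plot == "plot01"]
  d_clay <- ped$dist_to_mother[ped$plot == "plot02"]
  expect_gt(mean(d_sandy), 10 * mean(d_clay))
})

test_that("parameter recovery: class-1 r decreases with dispersal scale", {
  small <- sim_config(n_plots = 4, n_adults = 6,
                      cohort_sizes = c(FIRST_YEAR = 20, YOUNG = 0, SAPLING = 0))
  rec <- parameter_recovery_suite("dispersal", n_reps = 4, seed = 3, config = small,
                                  n_perm = 29, sigma_grid = c(5, 80))
  expect_true(rec$mean_r1[1] > rec$mean_r1[2])
  expect_equal(sgs_meta(rec)$ordering_ok, 1L)
})
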