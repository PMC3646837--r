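#' Configuration for the spatial genotype simulator
#'
#' Defines a landscape of parallel transect plots (default 14 plots of
#' 250 m x 40 m spaced 1 km apart, the layout of a systematic trail-grid
#' survey), a dioecious adult population, neutral multiallelic loci, and a
#' seed-dispersal model: each offspring takes its mother's position plus a
#' kernel displacement and may be thinned by distance-dependent
#' (Janzen-Connell) mortality, `P(survive at distance d from mother)
#' = 1 - exp(-d / lambda_jc)`.
#'
#' Defaults emulate the sampling design the analyses are built for: ~360
#' genotyped individuals in four ontogenetic classes across 14 plots, 7
#' microsatellite-like loci with 4-12 alleles each (mean 7.7), two soil
#' strata split at 15% clay with the per-plot clay percentages of a real
#' Amazonian plot network, and limited seed dispersal (sigma = 10 m) that
#' produces positive short-distance SGS.
#'
#' @param n_plots Number of plots.
#' @param plot_length,plot_width,plot_spacing Plot geometry in metres.
#' @param n_adults Adults per plot (the parental pool; all are also sampled
#'   as the `ADULT_JUVENILE` cohort).
#' @param adult_placement `"uniform"` or `"clustered"` (Gaussian about the
#'   plot centre, sd = `plot_length / 10`).
#' @param n_loci Number of loci.
#' @param n_alleles Alleles per locus (recycled to `n_loci`).
#' @param dirichlet_conc Symmetric Dirichlet concentration for the generator
#'   allele frequencies (1 = uniform over the simplex).
#' @param cohort_sizes Named per-plot offspring counts for the seedling
#'   cohorts (`FIRST_YEAR`, `YOUNG`, `SAPLING`).
#' @param kernel `"gaussian"` (axial sd `sigma`) or `"exponential"`
#'   (radial mean `sigma`, uniform direction).
#' @param sigma Dispersal scale in metres; `Inf` places offspring uniformly
#'   in the plot (no dispersal limitation).
#' @param jc Apply Janzen-Connell thinning?
#' @param lambda_jc JC scale in metres; scalar, or named per-cohort vector to
#'   let older cohorts carry a longer thinning history.
#' @param clay_pct Per-plot clay percentages (recycled to `n_plots`).
#' @param sigma_by_soil,lambda_by_soil Optional named overrides
#'   (`c(SANDY = ..., CLAY = ...)`) of `sigma` / `lambda_jc` per soil stratum.
#' @return A list of class `sgs_sim_config`.
#' @export
sim_config <- function(n_plots = 14,
                       plot_length = 250, plot_width = 40, plot_spacing = 1000,
                       n_adults = 4,
                       adult_placement = c("uniform", "clustered"),
                       n_loci = 7,
                       n_alleles = c(8, 12, 7, 9, 4, 4, 10),
                       dirichlet_conc = 1,
                       cohort_sizes = c(FIRST_YEAR = 10, YOUNG = 9, SAPLING = 4),
                       kernel = c("gaussian", "exponential"),
                       sigma = 10,
                       jc = FALSE, lambda_jc = 5,
                       clay_pct = c(2.68, 2.74, 3.79, 4.99, 11.81, 13.04, 32.24,
                                    42.57, 62.40, 72.46, 77.33, 78.28, 81.31, 83.30),
                       sigma_by_soil = NULL, lambda_by_soil = NULL) {
  cfg <- list(
    n_plots = n_plots, plot_length = plot_length, plot_width = plot_width,
    plot_spacing = plot_spacing, n_adults = n_adults,
    adult_placement = match.arg(adult_placement),
    n_loci = n_loci, n_alleles = rep_len(n_alleles, n_loci),
    dirichlet_conc = dirichlet_conc, cohort_sizes = cohort_sizes,
    kernel = match.arg(kernel), sigma = sigma,
    jc = jc, lambda_jc = lambda_jc,
    clay_pct = rep_len(clay_pct, n_plots),
    sigma_by_soil = sigma_by_soil, lambda_by_soil = lambda_by_soil
  )
  stopifnot(
    n_plots >= 1, plot_length > 0, plot_width > 0, plot_spacing > 0,
    n_adults >= 0, n_loci >= 1, all(cfg$n_alleles >= 1), dirichlet_conc > 0,
    all(cohort_sizes >= 0), sigma > 0, all(lambda_jc > 0),
    all(cfg$clay_pct >= 0 & cfg$clay_pct <= 100)
  )
  if (is.null(names(cfg$cohort_sizes)) ||
      !all(names(cfg$cohort_sizes) %in% c("FIRST_YEAR", "YOUNG", "SAPLING"))) {
    stop("cohort_sizes must be named with seedling size classes", call. = FALSE)
  }
  class(cfg) <- "sgs_sim_config"
  cfg
}

#' Simulate a spatially structured genotype dataset
#'
#' Forward simulation under the model described in [sim_config()]: adults are
#' drawn in Hardy-Weinberg proportions from Dirichlet-distributed generator
#' frequencies and placed in their plots; each offspring draws its mother
#' uniformly among the plot's females and its father uniformly among the
#' males (dioecious, no selfing), inherits one allele per parent per locus,
#' lands at its mother's position plus a kernel displacement, and survives
#' Janzen-Connell thinning by rejection. Cohorts are labelled
#' `FIRST_YEAR`/`YOUNG`/`SAPLING`; the adults form the `ADULT_JUVENILE`
#' class.
#'
#' @param config An [sim_config()] object.
#' @param seed Integer seed; the dataset is byte-identical for a given seed.
#' @return A list with `data` (an [sgs_data] tibble) and `truth` (generator
#'   record: `pedigree` tibble with mother/father ids and realised
#'   mother-offspring distances, `freqs` generator allele frequencies,
#'   `sexes`, `config`, `seed`). Tests should read pedigree facts from
#'   `truth`, never re-derive them from the data.
#' @export
simulate_population <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sgs_sim_config"))
  total_offspring <- sum(config$cohort_sizes)
  if (total_offspring > 0 && config$n_adults < 2) {
    stop("offspring requested but fewer than 2 adults per plot: ",
         "a dioecious plot needs at least one female and one male", call. = FALSE)
  }
  with_seed(seed, simulate_population_impl(config, seed))
}

simulate_population_impl <- function(config, seed) {
  loci <- paste0("loc", seq_len(config$n_loci))
  # generator allele frequencies: symmetric Dirichlet per locus; allele codes
  # styled as fragment sizes (100 + 2 * index)
  freqs <- purrr::map2_dfr(loci, config$n_alleles, function(l, k) {
    w <- stats::rgamma(k, shape = config$dirichlet_conc)
    tibble::tibble(locus = l, allele = 100L + 2L * seq_len(k), freq = w / sum(w))
  })

  soil <- as.character(classify_soil(config$clay_pct))
  param_for <- function(base, override, soil_class) {
    if (is.null(override)) return(base)
    v <- override[[soil_class]]
    if (is.null(v) || is.na(v)) base else v
  }

  geno <- list(); meta <- list(); ped <- list(); sexes <- list()
  for (pl in seq_len(config$n_plots)) {
    plot_id <- sprintf("plot%02d", pl)
    x0 <- (pl - 1) * config$plot_spacing
    nA <- config$n_adults
    sigma_pl <- param_for(config$sigma, config$sigma_by_soil, soil[pl])
    lambda_pl <- function(cohort) {
      lam <- config$lambda_jc
      lam <- if (!is.null(names(lam)) && cohort %in% names(lam)) lam[[cohort]] else lam[[1]]
      param_for(lam, config$lambda_by_soil, soil[pl])
    }

    # adults: positions, sexes (Bernoulli 1/2, redrawn until both sexes are
    # present when offspring are requested), Hardy-Weinberg genotypes
    if (config$adult_placement == "uniform") {
      ax <- x0 + stats::runif(nA, 0, config$plot_width)
      ay <- stats::runif(nA, 0, config$plot_length)
    } else {
      ax <- pmin(pmax(x0 + config$plot_width / 2 +
                        stats::rnorm(nA, 0, config$plot_width / 10), x0),
                 x0 + config$plot_width)
      ay <- pmin(pmax(config$plot_length / 2 +
                        stats::rnorm(nA, 0, config$plot_length / 10), 0),
                 config$plot_length)
    }
    need_both <- sum(config$cohort_sizes) > 0 && nA >= 2
    repeat {
      sex <- ifelse(stats::runif(nA) < 0.5, "F", "M")
      if (!need_both || (any(sex == "F") && any(sex == "M"))) break
    }
    adult_ids <- sprintf("%s_ad%02d", plot_id, seq_len(nA))
    adult_geno <- lapply(loci, function(l) {
      fr <- freqs[freqs$locus == l, ]
      matrix(sample(fr$allele, 2 * nA, replace = TRUE, prob = fr$freq), nA, 2)
    })
    names(adult_geno) <- loci

    g_ad <- tibble::tibble(id = adult_ids)
    for (l in loci) {
      g_ad[[paste0(l, ".a1")]] <- adult_geno[[l]][, 1]
      g_ad[[paste0(l, ".a2")]] <- adult_geno[[l]][, 2]
    }
    geno[[length(geno) + 1]] <- g_ad
    meta[[length(meta) + 1]] <- tibble::tibble(
      id = adult_ids, plot = plot_id, x = ax, y = ay,
      height_cm = NA_real_, clay_pct = config$clay_pct[pl],
      size_class = "ADULT_JUVENILE"
    )
    sexes[[length(sexes) + 1]] <- tibble::tibble(id = adult_ids, sex = sex)

    females <- which(sex == "F"); males <- which(sex == "M")
    for (cohort in names(config$cohort_sizes)) {
      m <- config$cohort_sizes[[cohort]]
      if (m == 0) next
      lam <- lambda_pl(cohort)
      got <- 0L; attempts <- 0L
      mo_k <- integer(m); fa_k <- integer(m); ox <- numeric(m); oy <- numeric(m)
      od <- numeric(m)
      while (got < m) {
        k <- m - got
        attempts <- attempts + k
        if (attempts > 10000L * m) {
          stop("Janzen-Connell thinning rejected virtually all offspring in ",
               plot_id, " cohort ", cohort, call. = FALSE)
        }
        mo <- sample(females, k, replace = TRUE)
        fa <- sample(males, k, replace = TRUE)
        if (is.infinite(sigma_pl)) {
          px <- x0 + stats::runif(k, 0, config$plot_width)
          py <- stats::runif(k, 0, config$plot_length)
        } else if (config$kernel == "gaussian") {
          px <- ax[mo] + stats::rnorm(k, 0, sigma_pl)
          py <- ay[mo] + stats::rnorm(k, 0, sigma_pl)
        } else {
          ang <- stats::runif(k, 0, 2 * pi)
          rad <- stats::rexp(k, rate = 1 / sigma_pl)
          px <- ax[mo] + rad * cos(ang)
          py <- ay[mo] + rad * sin(ang)
        }
        d <- sqrt((px - ax[mo])^2 + (py - ay[mo])^2)
        acc <- if (config$jc) stats::runif(k) < (1 - exp(-d / lam)) else rep(TRUE, k)
        n_acc <- sum(acc)
        if (n_acc) {
          idx <- got + seq_len(n_acc)
          mo_k[idx] <- mo[acc]; fa_k[idx] <- fa[acc]
          ox[idx] <- px[acc]; oy[idx] <- py[acc]; od[idx] <- d[acc]
          got <- got + n_acc
        }
      }
      off_ids <- sprintf("%s_%s%03d", plot_id, tolower(substr(cohort, 1, 2)), seq_len(m))
      g_off <- tibble::tibble(id = off_ids)
      for (l in loci) {
        gm <- adult_geno[[l]]
        from_mo <- gm[cbind(mo_k, sample(1:2, m, replace = TRUE))]
        from_fa <- gm[cbind(fa_k, sample(1:2, m, replace = TRUE))]
        g_off[[paste0(l, ".a1")]] <- from_mo
        g_off[[paste0(l, ".a2")]] <- from_fa
      }
      height <- switch(cohort,
        FIRST_YEAR = stats::runif(m, 1, 20),
        YOUNG = 20 + stats::runif(m, .Machine$double.eps, 20),
        SAPLING = 40 + stats::runif(m, .Machine$double.eps, 60)
      )
      geno[[length(geno) + 1]] <- g_off
      meta[[length(meta) + 1]] <- tibble::tibble(
        id = off_ids, plot = plot_id, x = ox, y = oy,
        height_cm = height, clay_pct = config$clay_pct[pl],
        size_class = cohort
      )
      ped[[length(ped) + 1]] <- tibble::tibble(
        id = off_ids, mother = adult_ids[mo_k], father = adult_ids[fa_k],
        plot = plot_id, cohort = cohort, dist_to_mother = od
      )
    }
  }

  data <- sgs_data(dplyr::bind_rows(geno), dplyr::bind_rows(meta))
  list(
    data = data,
    truth = list(
      pedigree = if (length(ped)) dplyr::bind_rows(ped) else tibble::tibble(),
      freqs = freqs,
      sexes = dplyr::bind_rows(sexes),
      config = config,
      seed = seed
    )
  )
}

#' Parameter-recovery experiments for the simulator/analysis pipeline
#'
#' Runs small replicated simulation experiments that verify the pipeline
#' responds to the generative parameters in the expected direction:
#'
#' * `"dispersal"`: class-1 autocorrelation `r` across a dispersal-scale
#'   grid, with the permutation-envelope exceedance rate; `r` must decrease
#'   as `sigma` grows.
#' * `"jc"`: class-1 `r` of the first cohort versus a sapling cohort thinned
#'   by Janzen-Connell mortality; thinning must erode the sapling SGS.
#' * `"strata"`: power of the soil-strata heterogeneity `omega` test when the
#'   two strata have different dispersal scales.
#'
#' @param experiment Which experiment to run.
#' @param n_reps Replicates per grid cell.
#' @param seed Integer master seed (replicate seeds are derived from it).
#' @param config Base [sim_config()]; each experiment overrides the relevant
#'   fields.
#' @param edges Distance-class edges (metres).
#' @param n_perm Permutations per replicate for envelope/heterogeneity calls.
#' @param sigma_grid Dispersal scales for `"dispersal"` (metres).
#' @param lambda_grid JC scales for `"jc"` (metres).
#' @param sigma_by_soil Stratum dispersal scales for `"strata"`.
#' @param alpha Rejection level used for rates.
#' @return A tibble of class `sgs_recovery`, one row per grid cell with the
#'   cell's parameter value and the measured quantities; the `sgs_meta`
#'   attribute records the experiment and whether the expected ordering held
#'   (`ordering_ok`).
#' @export
parameter_recovery_suite <- function(experiment = c("dispersal", "jc", "strata"),
                                     n_reps = 20, seed = 1,
                                     config = sim_config(),
                                     edges = seq(50, 250, 50),
                                     n_perm = 199,
                                     sigma_grid = c(5, 20, 80),
                                     lambda_grid = c(5, 20),
                                     sigma_by_soil = c(SANDY = 40, CLAY = 10),
                                     alpha = 0.05) {
  experiment <- match.arg(experiment)
  rep_seed <- function(cell, r) (seed * 10007L + cell * 211L + r) %% .Machine$integer.max

  if (experiment == "dispersal") {
    rows <- purrr::imap_dfr(as.list(sigma_grid), function(sg, cell) {
      cfg <- config; cfg$sigma <- sg
      res <- purrr::map_dfr(seq_len(n_reps), function(r) {
        sim <- simulate_population(cfg, seed = rep_seed(cell, r))
        first <- dplyr::filter(sim$data, .data$size_class == "FIRST_YEAR")
        cg <- spatial_autocorrelation(first, edges, n_perm = n_perm, n_boot = 0,
                                      seed = rep_seed(cell, r) + 1L)
        tibble::tibble(r1 = cg$r[1], exceed = !is.na(cg$perm_hi[1]) & cg$r[1] > cg$perm_hi[1])
      })
      tibble::tibble(sigma = sg, mean_r1 = mean(res$r1, na.rm = TRUE),
                     se_r1 = stats::sd(res$r1, na.rm = TRUE) / sqrt(n_reps),
                     exceedance_rate = mean(res$exceed))
    })
    ok <- all(diff(rows$mean_r1) < 0)
    return(new_sgs_result(rows, "sgs_recovery",
                          meta = list(experiment = experiment, n_reps = n_reps,
                                      seed = seed, ordering_ok = as.integer(ok))))
  }

  if (experiment == "jc") {
    rows <- purrr::imap_dfr(as.list(lambda_grid), function(lam, cell) {
      cfg <- config
      cfg$jc <- TRUE
      # the sapling cohort carries the thinning history; the first cohort
      # is still unthinned (lambda ~ 0)
      cfg$lambda_jc <- c(FIRST_YEAR = 1e-6, YOUNG = 1e-6, SAPLING = lam)
      res <- purrr::map_dfr(seq_len(n_reps), function(r) {
        sim <- simulate_population(cfg, seed = rep_seed(cell, r))
        r1_of <- function(cls) {
          sub <- dplyr::filter(sim$data, .data$size_class == cls)
          spatial_autocorrelation(sub, edges, n_perm = 0, n_boot = 0)$r[1]
        }
        tibble::tibble(r1_first = r1_of("FIRST_YEAR"), r1_sapling = r1_of("SAPLING"))
      })
      tibble::tibble(lambda_jc = lam,
                     mean_r1_first = mean(res$r1_first, na.rm = TRUE),
                     mean_r1_sapling = mean(res$r1_sapling, na.rm = TRUE))
    })
    ok <- all(rows$mean_r1_sapling < rows$mean_r1_first)
    return(new_sgs_result(rows, "sgs_recovery",
                          meta = list(experiment = experiment, n_reps = n_reps,
                                      seed = seed, ordering_ok = as.integer(ok))))
  }

  # strata: sandy plots disperse farther than clay plots; the heterogeneity
  # omega test between soil classes should detect it
  cfg <- config; cfg$sigma_by_soil <- sigma_by_soil
  res <- purrr::map_dfr(seq_len(n_reps), function(r) {
    sim <- simulate_population(cfg, seed = rep_seed(1L, r))
    seedl <- dplyr::filter(sim$data, .data$size_class %in% c("FIRST_YEAR", "YOUNG"))
    het <- correlogram_heterogeneity(seedl, "soil_class", groups = c("SANDY", "CLAY"),
                                     edges = edges, n_perm = n_perm,
                                     seed = rep_seed(1L, r) + 1L, permute_by = "plot")
    tibble::tibble(p_omega = sgs_meta(het)$p_omega)
  })
  rows <- tibble::tibble(sigma_sandy = sigma_by_soil[["SANDY"]],
                         sigma_clay = sigma_by_soil[["CLAY"]],
                         power = mean(res$p_omega < alpha, na.rm = TRUE))
  new_sgs_result(rows, "sgs_recovery",
                 meta = list(experiment = experiment, n_reps = n_reps,
                             seed = seed, ordering_ok = as.integer(rows$power > 0)))
}
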