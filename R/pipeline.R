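#' Ontogenetic size class from plant height
#'
#' Height bands on a continuous scale: `[0, 20]` cm first-year seedlings,
#' `(20, 40]` young seedlings, `(40, 100]` saplings, `(100, 200]` excluded
#' (too few individuals to analyse in the design this reproduces), and
#' `> 200` cm juveniles and adults.
#'
#' @param height_cm Numeric heights in cm (`NA` allowed, returned as `NA`).
#' @return Factor with levels `FIRST_YEAR`, `YOUNG`, `SAPLING`,
#'   `ADULT_JUVENILE`, `EXCLUDED`.
#' @export
assign_size_class <- function(height_cm) {
  height_cm <- as.numeric(height_cm)
  if (any(height_cm < 0, na.rm = TRUE)) stop("negative height", call. = FALSE)
  out <- rep(NA_character_, length(height_cm))
  ok <- !is.na(height_cm)
  h <- height_cm[ok]
  out[ok] <- dplyr::case_when(
    h <= 20 ~ "FIRST_YEAR",
    h <= 40 ~ "YOUNG",
    h <= 100 ~ "SAPLING",
    h <= 200 ~ "EXCLUDED",
    TRUE ~ "ADULT_JUVENILE"
  )
  factor(out, levels = size_class_levels)
}

#' Soil class from clay content
#'
#' Below 15% clay the soil is `SANDY`, above 15% `CLAY`. Exactly 15% is
#' classified `SANDY` (a declared tie-break: the defining phrases "less than
#' 15%" and "greater than 15%" leave the boundary open).
#'
#' @param clay_pct Clay percentages in `[0, 100]` (`NA` allowed).
#' @return Factor with levels `SANDY`, `CLAY`.
#' @export
classify_soil <- function(clay_pct) {
  clay_pct <- as.numeric(clay_pct)
  if (any(clay_pct < 0 | clay_pct > 100, na.rm = TRUE)) {
    stop("clay_pct outside [0, 100]", call. = FALSE)
  }
  out <- rep(NA_character_, length(clay_pct))
  ok <- !is.na(clay_pct)
  out[ok] <- ifelse(clay_pct[ok] <= 15, "SANDY", "CLAY")
  factor(out, levels = soil_class_levels)
}

#' Keep only plots with enough individuals for pairwise analysis
#'
#' Pairwise statistics need pairs: a plot is retained when at least one size
#' class holds at least `min_per_class` individuals.
#'
#' @param data An [sgs_data] tibble.
#' @param min_per_class Minimum class size (default 2).
#' @return The filtered tibble (same class); retained plot ids in the
#'   `kept_plots` attribute.
#' @export
filter_analysis_plots <- function(data, min_per_class = 2) {
  counts <- data |>
    dplyr::filter(!is.na(.data$size_class), .data$size_class != "EXCLUDED") |>
    dplyr::count(.data$plot, .data$size_class)
  keep <- unique(counts$plot[counts$n >= min_per_class])
  out <- data[data$plot %in% keep, , drop = FALSE]
  attr(out, "kept_plots") <- sort(keep)
  out
}

#' Run the full spatial-genetic-structure study
#'
#' One-call orchestration of every analysis the package implements, on one
#' dataset: genetic diversity by size class and by soil class; per-size-class
#' autocorrelation correlograms at coarse (50 m) edges; pooled correlograms
#' (seedlings up to 40 cm, plants above 40 cm, and everyone) at fine (10 m)
#' edges; all pairwise size-class heterogeneity tests; soil-stratified
#' pooled-seedling correlograms and the sand-versus-clay heterogeneity test;
#' and within- plus between-generation kinship profiles per seedling class.
#' The plot filter ([filter_analysis_plots()]) is applied first; `EXCLUDED`
#' individuals (100-200 cm) are dropped from every analysis. The orchestrator
#' only composes exported module functions, so running any stage separately
#' with the same seed reproduces its table.
#'
#' @param data An [sgs_data] tibble.
#' @param edges_coarse,edges_fine Distance-class edges in metres.
#' @param n_perm,n_boot Permutation/bootstrap replicate counts.
#' @param seed Integer seed; stage seeds are derived deterministically.
#' @param min_per_class Plot-inclusion rule passed to
#'   [filter_analysis_plots()].
#' @return A list of class `sgs_study` with elements `diversity_size`,
#'   `diversity_soil`, `correlograms` (per size class), `pooled` (three fine
#'   correlograms), `het_size` (named per class pair), `soil_correlograms`,
#'   `het_soil`, `kinship` (within/between per class), and `log` (provenance
#'   tibble). Write it with [write_study_bundle()].
#' @export
run_study <- function(data,
                      edges_coarse = seq(50, 250, 50),
                      edges_fine = seq(10, 250, 10),
                      n_perm = 999, n_boot = 999, seed = 1,
                      min_per_class = 2) {
  data <- filter_analysis_plots(data, min_per_class)
  data <- dplyr::filter(data, .is_not_na_class(.data$size_class))
  stage_seed <- local({
    counter <- 0L
    function() {
      counter <<- counter + 1L
      (seed * 1009L + counter) %% .Machine$integer.max
    }
  })
  classes <- c("FIRST_YEAR", "YOUNG", "SAPLING", "ADULT_JUVENILE")
  present <- classes[classes %in% as.character(data$size_class)]
  sub <- function(cls) dplyr::filter(data, .data$size_class %in% cls)

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("study stage `", name, "` failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  diversity_size <- run_stage("diversity_size", diversity_summary(data, "size_class"))
  diversity_soil <- run_stage("diversity_soil", diversity_summary(data, "soil_class"))

  correlograms <- lapply(stats::setNames(present, present), function(cl) {
    run_stage(paste0("correlogram_", cl),
              spatial_autocorrelation(sub(cl), edges_coarse, n_perm, n_boot,
                                      seed = stage_seed()))
  })

  pooled_sets <- list(
    seedlings_le40 = c("FIRST_YEAR", "YOUNG"),
    plants_gt40 = c("SAPLING", "ADULT_JUVENILE"),
    all_individuals = classes
  )
  pooled <- lapply(pooled_sets, function(cls) {
    run_stage("pooled_correlogram",
              spatial_autocorrelation(sub(cls), edges_fine, n_perm, n_boot,
                                      seed = stage_seed()))
  })

  het_size <- list()
  if (length(present) >= 2) {
    for (a in seq_len(length(present) - 1)) {
      for (b in (a + 1):length(present)) {
        nm <- paste(present[a], present[b], sep = "_vs_")
        het_size[[nm]] <- run_stage(paste0("het_", nm),
          correlogram_heterogeneity(sub(c(present[a], present[b])), "size_class",
                                    groups = present[c(a, b)], edges = edges_coarse,
                                    n_perm = n_perm, seed = stage_seed()))
      }
    }
  }

  seedlings <- sub(c("FIRST_YEAR", "YOUNG"))
  soils <- intersect(soil_class_levels, as.character(seedlings$soil_class))
  soil_correlograms <- lapply(stats::setNames(soils, soils), function(sc) {
    run_stage(paste0("correlogram_soil_", sc),
      spatial_autocorrelation(dplyr::filter(seedlings, .data$soil_class == sc),
                              edges_coarse, n_perm, n_boot, seed = stage_seed()))
  })
  het_soil <- NULL
  if (length(soils) == 2) {
    # soil is a plot attribute: permute plots when there are enough of them,
    # otherwise fall back to the individual-level shuffle
    plots_per_soil <- seedlings |>
      dplyr::distinct(.data$plot, .data$soil_class) |>
      dplyr::count(.data$soil_class)
    unit <- if (all(plots_per_soil$n >= 2)) "plot" else "individual"
    het_soil <- run_stage("het_soil",
      correlogram_heterogeneity(seedlings, "soil_class", groups = c("SANDY", "CLAY"),
                                edges = edges_coarse, n_perm = n_perm,
                                seed = stage_seed(), permute_by = unit))
  }

  kin_classes <- intersect(c("FIRST_YEAR", "YOUNG", "SAPLING"), present)
  reference <- allele_frequencies(data)
  kinship <- list()
  for (cl in kin_classes) {
    kinship[[paste0("within_", cl)]] <- run_stage(paste0("kinship_within_", cl),
      kinship_correlogram(data, edges_coarse, mode = "within", focal_class = cl,
                          reference = reference))
    if ("ADULT_JUVENILE" %in% present) {
      kinship[[paste0("between_", cl)]] <- run_stage(paste0("kinship_between_", cl),
        kinship_correlogram(data, edges_coarse, mode = "between", focal_class = cl,
                            reference = reference))
    }
  }
  kinship[["all"]] <- run_stage("kinship_all",
    kinship_correlogram(data, edges_coarse, mode = "all", reference = reference))

  log <- tibble::tibble(
    key = c("package", "seed", "n_perm", "n_boot", "n_individuals", "n_plots",
            "edges_coarse", "edges_fine", "date"),
    value = c(paste("sgsr", utils::packageVersion("sgsr")), seed, n_perm, n_boot,
              nrow(data), length(unique(data$plot)),
              paste(edges_coarse, collapse = ","), paste(edges_fine, collapse = ","),
              format(Sys.Date()))
  )

  structure(list(
    diversity_size = diversity_size, diversity_soil = diversity_soil,
    correlograms = correlograms, pooled = pooled, het_size = het_size,
    soil_correlograms = soil_correlograms, het_soil = het_soil,
    kinship = kinship, log = log
  ), class = "sgs_study")
}

.is_not_na_class <- function(x) !is.na(x) & x != "EXCLUDED"

#' Write every table of a study bundle to a directory
#'
#' @param bundle An `sgs_study` list from [run_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sgs_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(obj, name) {
    p <- file.path(dir, paste0(name, ".tsv"))
    write_sgs_table(obj, p)
    paths <<- c(paths, p)
  }
  emit(bundle$diversity_size, "diversity_size")
  emit(bundle$diversity_soil, "diversity_soil")
  for (nm in names(bundle$correlograms)) emit(bundle$correlograms[[nm]], paste0("correlogram_", nm))
  for (nm in names(bundle$pooled)) emit(bundle$pooled[[nm]], paste0("correlogram_", nm))
  for (nm in names(bundle$het_size)) emit(bundle$het_size[[nm]], paste0("het_", nm))
  for (nm in names(bundle$soil_correlograms)) emit(bundle$soil_correlograms[[nm]], paste0("correlogram_soil_", nm))
  if (!is.null(bundle$het_soil)) emit(bundle$het_soil, "het_soil")
  for (nm in names(bundle$kinship)) emit(bundle$kinship[[nm]], paste0("kinship_", nm))
  readr::write_tsv(bundle$log, file.path(dir, "provenance.tsv"))
  invisible(c(paths, file.path(dir, "provenance.tsv")))
}
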