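#' Assemble a spatial genotype table
#'
#' Combines a codominant genotype table with per-individual coordinates and
#' metadata into the single tibble every analysis in the package consumes.
#' Genotypes are diploid microsatellite-style allele calls stored as a pair of
#' integer columns `<locus>.a1` / `<locus>.a2` per locus; coordinates are
#' planar metres.
#'
#' Missing data convention: an allele coded `0`, `NA` or blank is missing, and
#' a half-missing genotype (only one allele called) is treated as fully missing
#' at that locus, because every downstream statistic works on diploid dosage
#' vectors that must sum to 2.
#'
#' @param genotypes Data frame with column `id` and two allele columns per
#'   locus named `<locus>.a1` and `<locus>.a2`.
#' @param meta Data frame keyed by `id` with coordinates `x`, `y` (metres) and
#'   optionally `plot`, `height_cm`, `clay_pct`, `size_class`, `soil_class`.
#'   An explicit `size_class` column overrides classification from
#'   `height_cm` (adults are often recorded by DBH, not height).
#' @return A tibble of class `sgs_data`: one row per individual, metadata
#'   columns first, then the locus columns.
#' @seealso [read_genotypes()], [assign_size_class()], [classify_soil()]
#' @export
sgs_data <- function(genotypes, meta) {
  genotypes <- tibble::as_tibble(genotypes)
  meta <- tibble::as_tibble(meta)
  if (!"id" %in% names(genotypes) || !"id" %in% names(meta)) {
    stop("both `genotypes` and `meta` need an `id` column", call. = FALSE)
  }
  genotypes$id <- as.character(genotypes$id)
  meta$id <- as.character(meta$id)
  if (anyDuplicated(genotypes$id)) {
    stop("duplicated individual id(s) in genotype table: ",
         paste(unique(genotypes$id[duplicated(genotypes$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(meta$id)) {
    stop("duplicated individual id(s) in meta table: ",
         paste(unique(meta$id[duplicated(meta$id)]), collapse = ", "),
         call. = FALSE)
  }
  only_g <- setdiff(genotypes$id, meta$id)
  only_m <- setdiff(meta$id, genotypes$id)
  if (length(only_g) || length(only_m)) {
    stop("individuals present in one file only; genotypes-only: [",
         paste(only_g, collapse = ", "), "] meta-only: [",
         paste(only_m, collapse = ", "), "]", call. = FALSE)
  }
  loci <- detect_loci(genotypes)
  if (!length(loci)) stop("no `<locus>.a1`/`<locus>.a2` column pairs found", call. = FALSE)
  stray <- setdiff(names(genotypes), c("id", paste0(rep(loci, each = 2), c(".a1", ".a2"))))
  if (length(stray)) {
    stop("unpaired allele column(s): ", paste(stray, collapse = ", "),
         " (each locus needs exactly two columns, `.a1` and `.a2`)", call. = FALSE)
  }

  out <- dplyr::left_join(meta, genotypes, by = "id")
  out <- normalise_meta(out)
  for (l in loci) {
    a1 <- code_alleles(out[[paste0(l, ".a1")]])
    a2 <- code_alleles(out[[paste0(l, ".a2")]])
    half <- xor(is.na(a1), is.na(a2))
    a1[half] <- NA_integer_
    a2[half] <- NA_integer_
    out[[paste0(l, ".a1")]] <- a1
    out[[paste0(l, ".a2")]] <- a2
  }
  out <- dplyr::relocate(out, "id")
  validate_sgs_data(out)
  class(out) <- c("sgs_data", class(tibble::tibble()))
  out
}

#' Locus names of a spatial genotype table
#'
#' @param data An `sgs_data` tibble (or any data frame with paired
#'   `<locus>.a1`/`<locus>.a2` columns).
#' @return Character vector of locus names, in column order.
#' @export
sgs_loci <- function(data) detect_loci(data)

detect_loci <- function(data) {
  nm <- names(data)
  l1 <- sub("\\.a1$", "", nm[grepl("\\.a1$", nm)])
  l2 <- sub("\\.a2$", "", nm[grepl("\\.a2$", nm)])
  intersect(l1, l2)
}

code_alleles <- function(x) {
  x <- suppressWarnings(as.integer(as.character(x)))
  x[!is.na(x) & x == 0L] <- NA_integer_
  x
}

size_class_levels <- c("FIRST_YEAR", "YOUNG", "SAPLING", "ADULT_JUVENILE", "EXCLUDED")
soil_class_levels <- c("SANDY", "CLAY")

normalise_meta <- function(out) {
  for (col in c("x", "y")) {
    if (!col %in% names(out)) stop("meta table lacks coordinate column `", col, "`", call. = FALSE)
    out[[col]] <- as.numeric(out[[col]])
    if (any(!is.finite(out[[col]]))) stop("non-finite coordinate in `", col, "`", call. = FALSE)
  }
  if (!"plot" %in% names(out)) out$plot <- "plot1"
  out$plot <- as.character(out$plot)
  if ("height_cm" %in% names(out)) {
    out$height_cm <- as.numeric(out$height_cm)
    if (any(out$height_cm < 0, na.rm = TRUE)) stop("negative height_cm", call. = FALSE)
  } else {
    out$height_cm <- NA_real_
  }
  if ("clay_pct" %in% names(out)) {
    out$clay_pct <- as.numeric(out$clay_pct)
    bad <- !is.na(out$clay_pct) & (out$clay_pct < 0 | out$clay_pct > 100)
    if (any(bad)) stop("clay_pct outside [0, 100]", call. = FALSE)
  } else {
    out$clay_pct <- NA_real_
  }
  if ("size_class" %in% names(out)) {
    sc <- as.character(out$size_class)
    bad <- !is.na(sc) & !sc %in% size_class_levels
    if (any(bad)) stop("unknown size_class value(s): ", paste(unique(sc[bad]), collapse = ", "), call. = FALSE)
    miss <- is.na(sc) & !is.na(out$height_cm)
    sc[miss] <- as.character(assign_size_class(out$height_cm[miss]))
    out$size_class <- factor(sc, levels = size_class_levels)
  } else {
    out$size_class <- assign_size_class(out$height_cm)
  }
  if ("soil_class" %in% names(out)) {
    so <- as.character(out$soil_class)
    bad <- !is.na(so) & !so %in% soil_class_levels
    if (any(bad)) stop("unknown soil_class value(s): ", paste(unique(so[bad]), collapse = ", "), call. = FALSE)
    out$soil_class <- factor(so, levels = soil_class_levels)
  } else {
    out$soil_class <- classify_soil(out$clay_pct)
  }
  out
}

validate_sgs_data <- function(data) {
  loci <- detect_loci(data)
  for (l in loci) {
    a1 <- data[[paste0(l, ".a1")]]
    a2 <- data[[paste0(l, ".a2")]]
    if (any(xor(is.na(a1), is.na(a2)))) {
      stop("half-missing genotype left at locus ", l, call. = FALSE)
    }
  }
  invisible(data)
}

# Per-locus allele dosage encoding: for locus l, a list with the sorted allele
# registry and the n x A matrix of allele counts per individual (rows of
# missing genotypes are zero, flagged by `present`). Dosage rows sum to 2.
locus_dosage <- function(data, locus) {
  a1 <- data[[paste0(locus, ".a1")]]
  a2 <- data[[paste0(locus, ".a2")]]
  alleles <- sort(unique(c(a1, a2)))
  alleles <- alleles[!is.na(alleles)]
  n <- nrow(data)
  Q <- matrix(0, n, max(length(alleles), 1L),
              dimnames = list(data$id, as.character(alleles)))
  present <- !is.na(a1)
  if (length(alleles)) {
    i1 <- match(a1, alleles)
    i2 <- match(a2, alleles)
    ok <- which(present)
    for (i in ok) {
      Q[i, i1[i]] <- Q[i, i1[i]] + 1
      Q[i, i2[i]] <- Q[i, i2[i]] + 1
    }
  }
  list(alleles = alleles, Q = Q, present = present)
}

all_dosage <- function(data) {
  loci <- detect_loci(data)
  stats::setNames(lapply(loci, function(l) locus_dosage(data, l)), loci)
}

#' Project longitude/latitude to local planar metres
#'
#' Equirectangular projection about the dataset centroid; adequate for
#' landscapes spanning a few kilometres, where the distortion is far below
#' the width of any distance class.
#'
#' @param lon,lat Coordinates in decimal degrees.
#' @return Tibble with planar `x`, `y` in metres (centroid at the origin).
#' @export
lonlat_to_planar <- function(lon, lat) {
  r_earth <- 6371008.8
  lat0 <- mean(lat) * pi / 180
  tibble::tibble(
    x = (lon - mean(lon)) * pi / 180 * r_earth * cos(lat0),
    y = (lat - mean(lat)) * pi / 180 * r_earth
  )
}
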