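#' Read genotype and metadata tables from disk
#'
#' The canonical dialect is `"plain"`: a TSV genotype table with columns
#' `id, <locus>.a1, <locus>.a2, ...` plus a TSV metadata table with columns
#' `id, plot, x, y, height_cm, clay_pct` (and optionally `size_class`,
#' `soil_class`). The `"genalex"` dialect accepts the GenAlEx codominant
#' export layout: two header rows (counts, then title) followed by a header
#' line `Sample, Pop, <locus>, , <locus>, , ...` and one row per individual
#' with two allele columns per locus; the metadata table is still required
#' for coordinates. Allele `0` or blank is missing.
#'
#' @param genotype_path,meta_path Paths to the two tables.
#' @param dialect `"plain"` (default) or `"genalex"`.
#' @return An [sgs_data] tibble.
#' @export
read_genotypes <- function(genotype_path, meta_path, dialect = c("plain", "genalex")) {
  dialect <- match.arg(dialect)
  if (!file.exists(genotype_path)) stop("genotype file not found: ", genotype_path, call. = FALSE)
  if (!file.exists(meta_path)) stop("meta file not found: ", meta_path, call. = FALSE)
  geno <- switch(dialect,
    plain = read_plain_genotypes(genotype_path),
    genalex = read_genalex_genotypes(genotype_path)
  )
  meta <- readr::read_tsv(meta_path, comment = "#", show_col_types = FALSE)
  sgs_data(geno, meta)
}

read_plain_genotypes <- function(path) {
  g <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  allele_cols <- setdiff(names(g), "id")
  if (length(allele_cols) %% 2 != 0) {
    stop("odd number of allele columns (", length(allele_cols),
         "); each locus needs two", call. = FALSE)
  }
  g
}

read_genalex_genotypes <- function(path) {
  lines <- readr::read_lines(path)
  if (length(lines) < 4) stop("GenAlEx file too short", call. = FALSE)
  sep <- if (grepl("\t", lines[3])) "\t" else ","
  header <- strsplit(lines[3], sep, fixed = TRUE)[[1]]
  if (length(header) < 4) stop("GenAlEx header row not recognised", call. = FALSE)
  locus_pos <- seq(3L, length(header), by = 2L)
  loci <- trimws(header[locus_pos])
  loci <- loci[loci != ""]
  body <- utils::read.table(text = lines[-(1:3)], sep = sep, header = FALSE,
                            stringsAsFactors = FALSE, fill = TRUE)
  if (ncol(body) < 2 + 2 * length(loci)) {
    stop("odd number of allele columns in GenAlEx block", call. = FALSE)
  }
  out <- tibble::tibble(id = as.character(body[[1]]))
  for (k in seq_along(loci)) {
    out[[paste0(loci[k], ".a1")]] <- body[[2 + 2 * k - 1]]
    out[[paste0(loci[k], ".a2")]] <- body[[2 + 2 * k]]
  }
  out
}

#' Write a spatial genotype table to disk
#'
#' Writes the two canonical `"plain"`-dialect TSV files that
#' [read_genotypes()] reads back losslessly.
#'
#' @param data An [sgs_data] tibble.
#' @param genotype_path,meta_path Output paths.
#' @return `data`, invisibly.
#' @export
write_genotypes <- function(data, genotype_path, meta_path) {
  loci <- detect_loci(data)
  gcols <- c("id", paste0(rep(loci, each = 2), c(".a1", ".a2")))
  readr::write_tsv(data[, gcols], genotype_path, na = "")
  mcols <- intersect(
    c("id", "plot", "x", "y", "height_cm", "clay_pct", "size_class", "soil_class"),
    names(data)
  )
  readr::write_tsv(data[, mcols], meta_path, na = "")
  invisible(data)
}

#' Write an analysis result table to disk
#'
#' All result types (correlograms, kinship curves, heterogeneity tables,
#' diversity tables) are tibbles carrying scalar metadata (seed, permutation
#' counts, omega statistics, ...) in an `sgs_meta` attribute. The on-disk
#' format is TSV preceded by `#`-prefixed provenance lines
#' (`#key<TAB>value`), so [read_sgs_table()] restores the object exactly:
#' numeric fields use shortest round-trip representation.
#'
#' @param result A result tibble produced by this package.
#' @param path Output path.
#' @return `result`, invisibly.
#' @export
write_sgs_table <- function(result, path) {
  meta <- attr(result, "sgs_meta")
  cls <- class(result)[1]
  hdr <- c(
    paste0("#sgs_class\t", cls),
    paste0("#package\tsgsr ", as.character(utils::packageVersion("sgsr")))
  )
  for (k in names(meta)) {
    v <- meta[[k]]
    v <- if (is.numeric(v)) format_shortest(v) else as.character(v)
    hdr <- c(hdr, paste0("#meta:", k, "\t", paste(v, collapse = ",")))
  }
  body <- readr::format_tsv(tibble::as_tibble(result), na = "")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(sub("\n$", "", body), con, sep = "\n")
  invisible(result)
}

#' Read back a result table written by [write_sgs_table()]
#'
#' @param path Path to a TSV written by [write_sgs_table()].
#' @return The result tibble with its class and `sgs_meta` attribute restored.
#' @export
read_sgs_table <- function(path) {
  lines <- readr::read_lines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  out <- readr::read_tsv(I(paste(body, collapse = "\n")), show_col_types = FALSE, na = "")
  meta <- list()
  cls <- NULL
  for (h in hdr) {
    kv <- strsplit(sub("^#", "", h), "\t", fixed = TRUE)[[1]]
    if (length(kv) < 2) next
    if (kv[1] == "sgs_class") {
      cls <- kv[2]
    } else if (startsWith(kv[1], "meta:")) {
      key <- sub("^meta:", "", kv[1])
      vals <- strsplit(kv[2], ",", fixed = TRUE)[[1]]
      num <- suppressWarnings(as.numeric(vals))
      meta[[key]] <- if (!anyNA(num)) num else vals
    }
  }
  if (length(meta)) attr(out, "sgs_meta") <- meta
  if (!is.null(cls)) class(out) <- c(cls, class(out))
  out
}

format_shortest <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    for (d in 1:17) {
      s <- formatC(v, digits = d, format = "g")
      if (as.numeric(s) == v) return(s)
    }
    formatC(v, digits = 17, format = "g")
  }, character(1))
}

new_sgs_result <- function(df, class, meta = list()) {
  out <- tibble::as_tibble(df)
  attr(out, "sgs_meta") <- meta
  class(out) <- c(class, class(tibble::tibble()))
  out
}

#' Scalar metadata of a result table
#'
#' Every result tibble carries its scalar context (seed, permutation counts,
#' omega statistics, group labels, bias terms, ...) in an `sgs_meta`
#' attribute, preserved by [write_sgs_table()] / [read_sgs_table()].
#'
#' @param x A result tibble produced by this package.
#' @return Named list of metadata entries (`NULL` if absent).
#' @export
sgs_meta <- function(x) attr(x, "sgs_meta")
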