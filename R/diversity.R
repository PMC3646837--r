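#' Allele frequencies of a reference group
#'
#' Counts each non-missing diploid genotype as two gene copies; a
#' heterozygote contributes one copy to each of its alleles. A locus with no
#' non-missing call in the group is returned with zero gene copies and no
#' allele rows (it is unavailable for that group).
#'
#' @param data An [sgs_data] tibble.
#' @param group Optional logical or integer vector selecting the reference
#'   individuals (default: all rows).
#' @return A tibble with one row per locus x allele: `locus`, `allele`,
#'   `freq`, and `n_copies` (gene copies typed at that locus, constant within
#'   locus). Frequencies sum to 1 within each available locus.
#' @export
allele_frequencies <- function(data, group = NULL) {
  sub <- if (is.null(group)) data else data[group, , drop = FALSE]
  if (nrow(sub) == 0) stop("reference group is empty", call. = FALSE)
  loci <- detect_loci(sub)
  purrr::map_dfr(loci, function(l) {
    d <- locus_dosage(sub, l)
    copies <- 2L * sum(d$present)
    if (copies == 0L || !length(d$alleles)) {
      return(tibble::tibble(locus = l, allele = NA_integer_,
                            freq = NA_real_, n_copies = 0L))
    }
    counts <- colSums(d$Q[d$present, , drop = FALSE])
    tibble::tibble(locus = l, allele = d$alleles,
                   freq = unname(counts) / copies, n_copies = copies)
  })
}

#' Per-group genetic diversity summary
#'
#' For each group of the partition and each locus: allele count `Na`,
#' effective allele number `Ne = 1 / sum(p^2)`, observed heterozygosity `Ho`
#' (fraction heterozygous among non-missing genotypes), gene diversity
#' `He = 1 - sum(p^2)` (no small-sample correction, i.e. the plain GenAlEx
#' quantity; set `unbiased = TRUE` for the `2n/(2n-1)` corrected variant) and
#' fixation index `F = 1 - Ho/He` (blank where `He = 0`). Group values are
#' means over loci with standard errors `sd/sqrt(n_loci)`. Private alleles
#' are alleles observed in exactly one group of the partition; the frequency
#' reported is the mean frequency of the group's private alleles within that
#' group.
#'
#' @param data An [sgs_data] tibble.
#' @param group_by Column name to partition by (e.g. `"size_class"`,
#'   `"soil_class"`, `"plot"`), or `NULL` for a single pooled group.
#' @param unbiased Apply the `2n/(2n-1)` small-sample correction to He?
#'   Default `FALSE`.
#' @return A tibble of class `sgs_diversity`: one row per group with `n`,
#'   `na`, `na_se`, `ne`, `ne_se`, `pa`, `pa_freq`, `ho`, `ho_se`, `he`,
#'   `he_se`, `f`, `f_se`. Use [allele_frequencies()] for locus-level work.
#' @export
diversity_summary <- function(data, group_by = NULL, unbiased = FALSE) {
  if (is.null(group_by)) {
    groups <- list(ALL = rep(TRUE, nrow(data)))
  } else {
    if (!group_by %in% names(data)) stop("no column `", group_by, "`", call. = FALSE)
    g <- data[[group_by]]
    if (anyNA(g)) stop("grouping column `", group_by, "` has missing values; ",
                       "the partition must cover all individuals", call. = FALSE)
    lv <- if (is.factor(g)) intersect(levels(g), unique(as.character(g))) else sort(unique(as.character(g)))
    groups <- stats::setNames(lapply(lv, function(v) as.character(g) == v), lv)
  }
  loci <- detect_loci(data)

  freqs <- purrr::map(groups, function(sel) allele_frequencies(data, sel))
  seen <- purrr::imap_dfr(freqs, ~dplyr::mutate(dplyr::filter(.x, !is.na(.data$allele)),
                                                group = .y))
  n_groups_with <- seen |>
    dplyr::filter(.data$freq > 0) |>
    dplyr::distinct(.data$locus, .data$allele, .data$group) |>
    dplyr::count(.data$locus, .data$allele, name = "n_groups")

  rows <- purrr::imap_dfr(groups, function(sel, gname) {
    sub <- data[sel, , drop = FALSE]
    fr <- freqs[[gname]] |> dplyr::filter(!is.na(.data$allele), .data$freq > 0)
    per_locus <- purrr::map_dfr(loci, function(l) {
      fl <- fr[fr$locus == l, ]
      if (!nrow(fl)) {
        return(tibble::tibble(locus = l, na = NA_real_, ne = NA_real_,
                              ho = NA_real_, he = NA_real_, f = NA_real_))
      }
      sump2 <- sum(fl$freq^2)
      he <- 1 - sump2
      if (unbiased) {
        n2 <- fl$n_copies[1]
        if (n2 > 1) he <- he * n2 / (n2 - 1)
      }
      a1 <- sub[[paste0(l, ".a1")]]
      a2 <- sub[[paste0(l, ".a2")]]
      ok <- !is.na(a1)
      ho <- if (any(ok)) mean(a1[ok] != a2[ok]) else NA_real_
      tibble::tibble(locus = l, na = nrow(fl), ne = 1 / sump2, ho = ho, he = he,
                     f = ifelse(he > 0, 1 - ho / he, NA_real_))
    })
    priv <- fr |>
      dplyr::inner_join(n_groups_with, by = c("locus", "allele")) |>
      dplyr::filter(.data$n_groups == 1L)
    mean_se <- function(v) {
      v <- v[!is.na(v)]
      list(mean = mean(v), se = stats::sd(v) / sqrt(length(v)))
    }
    na_ <- mean_se(per_locus$na); ne_ <- mean_se(per_locus$ne)
    ho_ <- mean_se(per_locus$ho); he_ <- mean_se(per_locus$he)
    f_ <- mean_se(per_locus$f)
    # private alleles are relative to a partition: undefined for one group
    n_priv <- if (length(groups) > 1) nrow(priv) else 0L
    tibble::tibble(
      group = gname, n = nrow(sub),
      na = na_$mean, na_se = na_$se, ne = ne_$mean, ne_se = ne_$se,
      pa = n_priv, pa_freq = if (n_priv) mean(priv$freq) else NA_real_,
      ho = ho_$mean, ho_se = ho_$se, he = he_$mean, he_se = he_$se,
      f = f_$mean, f_se = f_$se
    )
  })
  new_sgs_result(rows, "sgs_diversity",
                 meta = list(group_by = if (is.null(group_by)) "none" else group_by,
                             n_loci = length(loci), unbiased = as.integer(unbiased)))
}
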