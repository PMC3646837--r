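#' Pairwise Loiselle kinship coefficients
#'
#' Multiallelic kinship estimator based on allele-frequency covariances. With
#' `q_ila` the dosage fraction of allele `a` at locus `l` in individual `i`
#' (0, 1/2 or 1) and `p_la` the reference frequency,
#' \deqn{F_{ij} = \frac{\sum_l \sum_a (q_{ila}-p_{la})(q_{jla}-p_{la}) +
#'   \sum_l \sum_a p_{la}(1-p_{la})/(n_l-1)}{\sum_l \sum_a p_{la}(1-p_{la})}}
#' where `n_l` is the number of gene copies behind the reference frequencies
#' at locus `l` (the small-sample term). Loci missing in either individual
#' are dropped from every sum for that pair. Relatedness for non-inbred
#' individuals is `2 * Fij`.
#'
#' @param data An [sgs_data] tibble.
#' @param reference Reference allele frequencies as returned by
#'   [allele_frequencies()]; default: frequencies of all individuals in
#'   `data` pooled.
#' @return Symmetric n x n matrix of `Fij` values, diagonal `NA`.
#' @export
loiselle_fij <- function(data, reference = NULL) {
  if (is.null(reference)) reference <- allele_frequencies(data)
  loci <- intersect(detect_loci(data), unique(reference$locus))
  if (!length(loci)) stop("reference covers none of the data's loci", call. = FALSE)
  n <- nrow(data)
  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  for (l in loci) {
    ref <- reference[reference$locus == l & !is.na(reference$allele), ]
    d <- locus_dosage(data, l)
    alleles <- sort(union(ref$allele, d$alleles))
    if (!length(alleles) || !nrow(ref)) next
    p <- stats::setNames(rep(0, length(alleles)), alleles)
    p[as.character(ref$allele)] <- ref$freq
    n_l <- ref$n_copies[1]
    Q <- matrix(0, n, length(alleles), dimnames = list(NULL, alleles))
    if (length(d$alleles)) Q[, as.character(d$alleles)] <- d$Q
    X <- sweep(Q / 2, 2, p)
    X[!d$present, ] <- 0
    M <- tcrossprod(as.numeric(d$present))
    s_l <- sum(p * (1 - p))
    b_l <- if (n_l > 1) s_l / (n_l - 1) else 0
    num <- num + tcrossprod(X) + b_l * M
    den <- den + s_l * M
  }
  if (all(den[upper.tri(den)] == 0)) {
    stop("all reference loci are monomorphic: kinship undefined", call. = FALSE)
  }
  fij <- ifelse(den > 0, num / den, NA_real_)
  diag(fij) <- NA_real_
  dimnames(fij) <- list(data$id, data$id)
  fij
}

#' Kinship-by-distance profile (within or between generations)
#'
#' Averages pairwise Loiselle kinship per geographic distance class for a
#' chosen pair mode: `"within"` uses pairs where both individuals belong to
#' the focal size class; `"between"` pairs each focal-class individual with
#' every `ADULT_JUVENILE` individual (the between-generation analysis:
#' seedling-to-adult relatedness); `"all"` uses every pair. Comparing the
#' within and between profiles of a cohort reveals whether seedlings share
#' parents inside or outside the sampled area.
#'
#' @param data An [sgs_data] tibble with a populated `size_class` column.
#' @param edges Upper distance-class edges in metres.
#' @param mode `"within"`, `"between"` or `"all"`.
#' @param focal_class Focal size class for `"within"`/`"between"` modes.
#' @param reference Reference frequencies (default: all of `data` pooled, so
#'   within- and between-generation curves share a common footing).
#' @param n_perm Optional permutations of genotypes among locations for a
#'   95% null envelope per class (default 0 = none).
#' @param seed Integer seed for the envelope.
#' @return A tibble of class `sgs_kinship_curve`: `class_lo`, `class_hi`,
#'   `n_pairs`, `fij` (mean Loiselle kinship), `r` (`= 2 * fij`), and
#'   `perm_lo`/`perm_hi` when `n_perm > 0`. Mode and reference policy are in
#'   the `sgs_meta` attribute.
#' @export
kinship_correlogram <- function(data, edges, mode = c("within", "between", "all"),
                                focal_class = NULL, reference = NULL,
                                n_perm = 0, seed = NULL) {
  mode <- match.arg(mode)
  check_edges(edges)
  supplied_ref <- !is.null(reference)
  fij <- loiselle_fij(data, reference)
  sc <- as.character(data$size_class)
  if (mode != "all") {
    if (is.null(focal_class)) stop("`focal_class` required for mode ", mode, call. = FALSE)
    if (!any(sc == focal_class, na.rm = TRUE)) {
      stop("no individuals in focal class ", focal_class, call. = FALSE)
    }
  }
  pairs <- pair_classes(data$x, data$y, edges)
  keep <- switch(mode,
    all = rep(TRUE, nrow(pairs)),
    within = sc[pairs$i] == focal_class & sc[pairs$j] == focal_class,
    between = (sc[pairs$i] == focal_class & sc[pairs$j] == "ADULT_JUVENILE") |
              (sc[pairs$j] == focal_class & sc[pairs$i] == "ADULT_JUVENILE")
  )
  keep[is.na(keep)] <- FALSE
  pairs <- pairs[keep, , drop = FALSE]
  if (mode == "between" && !any(sc == "ADULT_JUVENILE", na.rm = TRUE)) {
    stop("no ADULT_JUVENILE individuals for between-generation pairs", call. = FALSE)
  }
  K <- length(edges)
  f <- factor(pairs$class, levels = seq_len(K))
  vals <- fij[cbind(pairs$i, pairs$j)]
  n_pairs <- tabulate(pairs$class, nbins = K)
  mean_f <- as.numeric(tapply(vals, f, mean, default = NA_real_))

  perm_lo <- perm_hi <- rep(NA_real_, K)
  if (n_perm > 0 && nrow(pairs) > 0) {
    n <- nrow(data)
    null_f <- matrix(NA_real_, n_perm, K)
    with_seed(seed, {
      for (b in seq_len(n_perm)) {
        pm <- sample.int(n)
        null_f[b, ] <- as.numeric(tapply(fij[cbind(pm[pairs$i], pm[pairs$j])],
                                         f, mean, default = NA_real_))
      }
    })
    for (k in which(n_pairs > 0)) {
      perm_lo[k] <- stats::quantile(null_f[, k], 0.025, na.rm = TRUE, names = FALSE)
      perm_hi[k] <- stats::quantile(null_f[, k], 0.975, na.rm = TRUE, names = FALSE)
    }
  }

  out <- tibble::tibble(
    class_lo = c(0, edges[-K]), class_hi = edges,
    n_pairs = n_pairs, fij = mean_f, r = 2 * mean_f,
    perm_lo = perm_lo, perm_hi = perm_hi
  )
  new_sgs_result(out, "sgs_kinship_curve", meta = list(
    mode = mode, focal_class = if (is.null(focal_class)) "none" else focal_class,
    reference = if (supplied_ref) "supplied" else "pooled",
    n_perm = n_perm, seed = if (is.null(seed)) NA_real_ else seed, n = nrow(data)
  ))
}
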