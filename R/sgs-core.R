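#' Pairwise squared genetic distance for codominant genotypes
#'
#' Each genotype at a locus is encoded as its allele-dosage vector (entries
#' 0/1/2 summing to 2) and the per-locus squared distance is half the squared
#' Euclidean distance between dosage vectors, which reproduces the familiar
#' codominant distance table: identical genotypes 0, `AA-AB` 1, `AB-AC` 1,
#' `AB-CD` 2, `AA-BC` 3, `AA-BB` 4. Loci missing in either member of a pair
#' are dropped from the sum and the total is rescaled by
#' `n_loci_total / n_loci_complete` for that pair, the "interpolation" rule
#' that keeps the expectation unbiased under missingness at random.
#'
#' @param data An [sgs_data] tibble (>= 2 individuals, >= 1 locus).
#' @return A symmetric n x n matrix of squared genetic distances with zero
#'   diagonal; the per-pair count of complete loci is attached as attribute
#'   `"complete_loci"`.
#' @export
genetic_distance <- function(data) {
  n <- nrow(data)
  if (n < 2) stop("need at least 2 individuals", call. = FALSE)
  dos <- all_dosage(data)
  if (!length(dos)) stop("no loci found", call. = FALSE)
  L <- length(dos)
  D2 <- matrix(0, n, n)
  complete <- matrix(0L, n, n)
  for (d in dos) {
    Q <- d$Q
    ss <- rowSums(Q^2)
    dl <- 0.5 * (outer(ss, ss, "+")) - tcrossprod(Q)
    pp <- tcrossprod(as.numeric(d$present))
    D2 <- D2 + dl * pp
    complete <- complete + (pp > 0)
  }
  off <- complete == 0L & row(complete) != col(complete)
  if (any(off)) {
    w <- sort(which(off, arr.ind = TRUE)[1, ])
    stop("individuals ", data$id[w[1]], " and ", data$id[w[2]],
         " share no complete locus", call. = FALSE)
  }
  scale <- L / pmax(complete, 1L)
  D2 <- D2 * scale
  diag(D2) <- 0
  D2 <- (D2 + t(D2)) / 2
  dimnames(D2) <- list(data$id, data$id)
  attr(D2, "complete_loci") <- complete
  D2
}

#' Gower double-centering of a squared-distance matrix
#'
#' `c_ij = -1/2 (d2_ij - m_i - m_j + m)` with `m_i` the row means and `m` the
#' grand mean, so every row and column of the result sums to zero and the
#' diagonal carries each individual's contribution to the total variance.
#'
#' @param D2 Symmetric squared-distance matrix.
#' @return The centered covariance-like matrix (same dimensions).
#' @export
gower_center <- function(D2) {
  rm_ <- rowMeans(D2)
  -0.5 * (D2 - outer(rm_, rep(1, ncol(D2))) - outer(rep(1, nrow(D2)), colMeans(D2)) + mean(D2))
}

#' Distance-class index of pair distances
#'
#' Class 1 is the closed interval `[0, e1]`; class `k > 1` is `(e[k-1], e[k]]`.
#' Distances beyond the last edge get `NA` (the pair is excluded).
#'
#' @param d Numeric vector of ground distances (metres).
#' @param edges Strictly increasing, positive upper class edges (metres).
#' @return Integer class index per distance, `NA` beyond the last edge.
#' @export
distance_class <- function(d, edges) {
  check_edges(edges)
  cls <- findInterval(d, edges, left.open = TRUE) + 1L
  cls[cls > length(edges)] <- NA_integer_
  cls
}

check_edges <- function(edges) {
  if (!length(edges) || any(!is.finite(edges)) || any(edges <= 0) ||
      any(diff(edges) <= 0)) {
    stop("distance-class edges must be positive and strictly increasing", call. = FALSE)
  }
  invisible(edges)
}

# Unordered pair list with ground distance and class; pairs beyond the last
# edge are dropped (cross-plot pairs drop out automatically when plots are
# farther apart than the last edge).
pair_classes <- function(x, y, edges) {
  n <- length(x)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- sqrt((x[ij[, 1]] - x[ij[, 2]])^2 + (y[ij[, 1]] - y[ij[, 2]])^2)
  cls <- distance_class(d, edges)
  keep <- !is.na(cls)
  tibble::tibble(i = ij[keep, 1], j = ij[keep, 2], d = d[keep], class = cls[keep])
}

# Per-class autocorrelation r from a centered matrix and a pair/class table.
# Ordered-pair sums: numerator 2*sum c_ij over the class's unordered pairs,
# denominator sum over those pairs of (c_ii + c_jj) -- i.e. each individual's
# diagonal weighted by the number of times it is paired in the class.
r_by_class <- function(C, pairs, n_classes, perm = NULL) {
  i <- pairs$i; j <- pairs$j
  if (!is.null(perm)) { i <- perm[i]; j <- perm[j] }
  dC <- diag(C)
  num <- 2 * C[cbind(i, j)]
  den <- dC[i] + dC[j]
  s <- rowsum(cbind(num, den), pairs$class)
  present <- as.integer(rownames(s))
  num_k <- den_k <- numeric(n_classes)
  num_k[present] <- s[, 1]
  den_k[present] <- s[, 2]
  n_k <- tabulate(pairs$class, nbins = n_classes)
  ifelse(n_k > 0 & abs(den_k) > 1e-12 * max(abs(dC), 1e-300),
         num_k / den_k, NA_real_)
}

#' Multivariate spatial autocorrelation correlogram
#'
#' Smouse-Peakall autocorrelation `r` per geographic distance class, computed
#' from the Gower-centered squared genetic distance matrix, with a
#' permutation null (genotypes shuffled among the sampling locations),
#' bootstrap error bars (pairs within each class resampled with replacement)
#' and the multiclass Fisher criterion `omega = -2 * sum(log(p_k))` testing
#' "no autocorrelation at any distance".
#'
#' Per-class p-values are two-sided with add-one smoothing:
#' `p = (1 + #{|r* - mean(r*)| >= |r - mean(r*)|}) / (1 + n_perm)`; the
#' envelope columns give the one-sided reading (2.5% and 97.5% null
#' quantiles) so both conventions are visible. The p-value of `omega` uses
#' the permutational reference (each replicate's pseudo-p vector scored
#' against the full replicate set); the upper-tail chi-square approximation
#' on `2 * n_classes` degrees of freedom is reported alongside.
#'
#' @param data An [sgs_data] tibble (>= 3 individuals).
#' @param edges Upper distance-class edges in metres, e.g. `seq(50, 250, 50)`.
#' @param n_perm Permutations for the null envelope and p-values (default 999;
#'   0 skips inference).
#' @param n_boot Bootstrap replicates for the error bars (default 999; 0 skips).
#' @param seed Integer seed making the whole call reproducible.
#' @return A tibble of class `sgs_correlogram` with one row per distance
#'   class: `class_lo`, `class_hi`, `n_pairs`, `r`, `perm_lo`, `perm_hi`,
#'   `boot_lo`, `boot_hi`, `p`. Scalars (`omega`, `p_omega`,
#'   `p_omega_chisq`, `n_perm`, `n_boot`, `seed`, `n`) live in the
#'   `sgs_meta` attribute; see [glance.sgs_correlogram()].
#' @export
spatial_autocorrelation <- function(data, edges, n_perm = 999, n_boot = 999,
                                    seed = NULL) {
  check_edges(edges)
  n <- nrow(data)
  if (n < 3 && n_perm > 0) stop("need at least 3 individuals for permutation inference", call. = FALSE)
  D2 <- genetic_distance(data)
  C <- gower_center(D2)
  tr <- sum(diag(C))
  if (tr <= 1e-12 * n) stop("no genetic variance: all genotypes identical", call. = FALSE)
  pairs <- pair_classes(data$x, data$y, edges)
  K <- length(edges)
  n_pairs <- tabulate(pairs$class, nbins = K)
  r_obs <- r_by_class(C, pairs, K)

  perm_lo <- perm_hi <- p <- rep(NA_real_, K)
  omega <- p_omega <- p_omega_chisq <- NA_real_
  boot_lo <- boot_hi <- rep(NA_real_, K)

  with_seed(seed, {
    if (n_perm > 0 && nrow(pairs) > 0) {
      null_r <- matrix(NA_real_, n_perm, K)
      for (b in seq_len(n_perm)) {
        null_r[b, ] <- r_by_class(C, pairs, K, perm = sample.int(n))
      }
      defined <- which(n_pairs > 0 & !is.na(r_obs))
      for (k in defined) {
        nk <- null_r[, k]
        perm_lo[k] <- stats::quantile(nk, 0.025, na.rm = TRUE, names = FALSE)
        perm_hi[k] <- stats::quantile(nk, 0.975, na.rm = TRUE, names = FALSE)
        mu <- mean(nk, na.rm = TRUE)
        p[k] <- (1 + sum(abs(nk - mu) >= abs(r_obs[k] - mu), na.rm = TRUE)) / (1 + n_perm)
      }
      if (length(defined)) {
        omega <- -2 * sum(log(p[defined]))
        p_omega_chisq <- stats::pchisq(omega, df = 2 * length(defined), lower.tail = FALSE)
        # permutational reference for omega: score each replicate's r vector
        # against the whole replicate set to get a pseudo-p vector
        omega_null <- rep(NA_real_, n_perm)
        mu_k <- colMeans(null_r, na.rm = TRUE)
        for (b in seq_len(n_perm)) {
          pb <- vapply(defined, function(k) {
            nk <- null_r[, k]
            mean(abs(nk - mu_k[k]) >= abs(null_r[b, k] - mu_k[k]), na.rm = TRUE)
          }, numeric(1))
          omega_null[b] <- -2 * sum(log(pmax(pb, 1 / n_perm)))
        }
        p_omega <- (1 + sum(omega_null >= omega, na.rm = TRUE)) / (1 + n_perm)
      }
    }
    if (n_boot > 0) {
      dC <- diag(C)
      for (k in seq_len(K)) {
        pk <- pairs[pairs$class == k, ]
        if (nrow(pk) < 2) next
        num <- 2 * C[cbind(pk$i, pk$j)]
        den <- dC[pk$i] + dC[pk$j]
        rb <- vapply(seq_len(n_boot), function(b) {
          s <- sample.int(nrow(pk), replace = TRUE)
          sum(num[s]) / sum(den[s])
        }, numeric(1))
        boot_lo[k] <- stats::quantile(rb, 0.025, na.rm = TRUE, names = FALSE)
        boot_hi[k] <- stats::quantile(rb, 0.975, na.rm = TRUE, names = FALSE)
      }
    }
  })

  out <- tibble::tibble(
    class_lo = c(0, edges[-K]), class_hi = edges,
    n_pairs = n_pairs, r = r_obs,
    perm_lo = perm_lo, perm_hi = perm_hi,
    boot_lo = boot_lo, boot_hi = boot_hi, p = p
  )
  new_sgs_result(out, "sgs_correlogram", meta = list(
    omega = omega, p_omega = p_omega, p_omega_chisq = p_omega_chisq,
    n_perm = n_perm, n_boot = n_boot,
    seed = if (is.null(seed)) NA_real_ else seed, n = n
  ))
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(invisible(force(code)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  invisible(force(code))
}
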