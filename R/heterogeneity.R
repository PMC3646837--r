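#' Heterogeneity test between two correlograms
#'
#' Non-parametric comparison of the spatial autocorrelation profiles of two
#' groups of individuals (e.g. two size classes, or sandy- versus clay-soil
#' seedlings), using the pooled set as the null reference frame. Group
#' membership labels are permuted among the pooled individuals (locations and
#' genotypes stay fixed) keeping group sizes; each replicate yields the two
#' group correlograms under the null of a single common pattern.
#'
#' The per-class statistic is
#' `t2_k = ((r_Ak - mu_Ak) - (r_Bk - mu_Bk))^2 / (V_Ak + V_Bk)`,
#' where `mu_gk` and `V_gk` are the mean and variance of group `g`'s class-k
#' `r` over the label permutations. Centering each group's `r` by its own
#' null mean is the sample-size weighted bias correction: the null expectation
#' of `r` is approximately `-1/(N_g - 1)` and therefore differs between
#' unequal groups. The whole-correlogram criterion is
#' `omega = -2 * sum(log(p_k))` with its p-value taken from the same label
#' permutations (chi-square upper tail on `2 * n_classes` df reported
#' alongside).
#'
#' @param data An [sgs_data] tibble containing both groups.
#' @param group_by Column that defines the two groups.
#' @param groups Length-2 character vector naming the two levels to compare;
#'   defaults to the two levels present (error if not exactly two).
#' @param edges Upper distance-class edges in metres.
#' @param n_perm Label permutations (default 999).
#' @param seed Integer seed.
#' @param permute_by Exchangeable unit for the label permutation:
#'   `"individual"` (default; right for groupings interleaved within plots,
#'   such as size classes) or `"plot"`, which reassigns whole plots to
#'   groups and is the calibrated choice when the grouping is a plot
#'   attribute (such as soil class) — shuffling individuals ignores
#'   plot-level family structure and is anticonservative there.
#' @return A tibble of class `sgs_heterogeneity` with one row per distance
#'   class: `class_lo`, `class_hi`, `n_pairs_a`, `n_pairs_b`, `r_a`, `r_b`,
#'   `t2`, `p`. The `sgs_meta` attribute carries `group_a`, `group_b`,
#'   `omega`, `p_omega`, `p_omega_chisq`, `n_perm`, `seed` and the per-class
#'   bias (`bias_a`, `bias_b`) and null-variance (`var_a`, `var_b`) terms.
#' @export
correlogram_heterogeneity <- function(data, group_by, groups = NULL, edges,
                                      n_perm = 999, seed = NULL,
                                      permute_by = c("individual", "plot")) {
  permute_by <- match.arg(permute_by)
  check_edges(edges)
  if (!group_by %in% names(data)) stop("no column `", group_by, "`", call. = FALSE)
  g <- as.character(data[[group_by]])
  if (is.null(groups)) {
    groups <- sort(unique(g[!is.na(g)]))
    if (length(groups) != 2) {
      stop("`", group_by, "` has ", length(groups),
           " levels present; pass `groups` naming exactly two", call. = FALSE)
    }
  }
  keep <- !is.na(g) & g %in% groups
  pooled <- data[keep, , drop = FALSE]
  g <- g[keep]
  nA <- sum(g == groups[1]); nB <- sum(g == groups[2])
  if (nA < 3 || nB < 3) stop("each group needs at least 3 individuals", call. = FALSE)
  n <- nA + nB
  K <- length(edges)

  D2 <- genetic_distance(pooled)
  # geographic class per pooled pair, computed once
  dx <- outer(pooled$x, pooled$x, "-"); dy <- outer(pooled$y, pooled$y, "-")
  clsM <- matrix(distance_class(sqrt(dx^2 + dy^2), edges), n, n)
  diag(clsM) <- NA_integer_

  group_r <- function(idx) {
    Csub <- gower_center(D2[idx, idx, drop = FALSE])
    m <- length(idx)
    ut <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
    cls <- clsM[idx, idx][upper.tri(matrix(0, m, m))]
    ok <- !is.na(cls)
    pr <- tibble::tibble(i = ut[ok, 1], j = ut[ok, 2], class = cls[ok])
    list(r = r_by_class(Csub, pr, K), n_pairs = tabulate(pr$class, nbins = K))
  }

  idxA <- which(g == groups[1]); idxB <- which(g == groups[2])
  obsA <- group_r(idxA); obsB <- group_r(idxB)

  if (permute_by == "plot") {
    plot_of <- split(seq_len(n), pooled$plot)
    plot_grp <- vapply(plot_of, function(ix) {
      u <- unique(g[ix])
      if (length(u) != 1) {
        stop("permute_by = \"plot\" needs each plot wholly inside one group",
             call. = FALSE)
      }
      u
    }, character(1))
    nplA <- sum(plot_grp == groups[1]); nplB <- sum(plot_grp == groups[2])
    if (nplA < 2 || nplB < 2) {
      stop("plot-level permutation needs at least 2 plots per group", call. = FALSE)
    }
    n_units <- length(plot_of)
    n_small <- min(nplA, nplB)
    a_is_small <- nplA <= nplB
    draw_partition <- function() {
      perm <- sample.int(n_units)
      small <- unlist(plot_of[perm[seq_len(n_small)]], use.names = FALSE)
      big <- unlist(plot_of[perm[-seq_len(n_small)]], use.names = FALSE)
      if (a_is_small) list(small, big) else list(big, small)
    }
    equal_sizes <- nplA == nplB
  } else {
    n_small <- min(nA, nB)
    a_is_small <- nA <= nB
    draw_partition <- function() {
      perm <- sample.int(n)
      small <- perm[seq_len(n_small)]
      big <- perm[-seq_len(n_small)]
      if (a_is_small) list(small, big) else list(big, small)
    }
    equal_sizes <- nA == nB
  }

  # canonical partition: the smaller group always fills from the head of the
  # permutation, so swapping the two labels reproduces the identical
  # replicate partitions and the test is exactly symmetric
  nullA <- matrix(NA_real_, max(n_perm, 1), K)
  nullB <- matrix(NA_real_, max(n_perm, 1), K)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      part <- draw_partition()
      nullA[b, ] <- group_r(part[[1]])$r
      nullB[b, ] <- group_r(part[[2]])$r
    }
  })

  if (equal_sizes) {
    # equal group sizes share one finite-sample bias: pool the two null sets
    pool <- rbind(nullA, nullB)
    muA <- muB <- colMeans(pool, na.rm = TRUE)
    vA <- vB <- apply(pool, 2, stats::var, na.rm = TRUE)
  } else {
    muA <- colMeans(nullA, na.rm = TRUE); muB <- colMeans(nullB, na.rm = TRUE)
    vA <- apply(nullA, 2, stats::var, na.rm = TRUE)
    vB <- apply(nullB, 2, stats::var, na.rm = TRUE)
  }

  t2_of <- function(rA, rB) {
    denom <- vA + vB
    out <- ((rA - muA) - (rB - muB))^2 / denom
    out[!is.finite(out)] <- NA_real_
    out
  }
  t2_obs <- t2_of(obsA$r, obsB$r)
  t2_obs[obsA$n_pairs == 0 | obsB$n_pairs == 0] <- NA_real_

  p <- rep(NA_real_, K)
  omega <- p_omega <- p_omega_chisq <- NA_real_
  if (n_perm > 0) {
    t2_null <- matrix(NA_real_, n_perm, K)
    for (b in seq_len(n_perm)) t2_null[b, ] <- t2_of(nullA[b, ], nullB[b, ])
    defined <- which(!is.na(t2_obs))
    for (k in defined) {
      p[k] <- (1 + sum(t2_null[, k] >= t2_obs[k], na.rm = TRUE)) / (1 + n_perm)
    }
    if (length(defined)) {
      omega <- -2 * sum(log(p[defined]))
      p_omega_chisq <- stats::pchisq(omega, df = 2 * length(defined), lower.tail = FALSE)
      omega_null <- vapply(seq_len(n_perm), function(b) {
        pb <- vapply(defined, function(k) {
          mean(t2_null[, k] >= t2_null[b, k], na.rm = TRUE)
        }, numeric(1))
        -2 * sum(log(pmax(pb, 1 / n_perm)), na.rm = TRUE)
      }, numeric(1))
      p_omega <- (1 + sum(omega_null >= omega, na.rm = TRUE)) / (1 + n_perm)
    }
  }

  out <- tibble::tibble(
    class_lo = c(0, edges[-K]), class_hi = edges,
    n_pairs_a = obsA$n_pairs, n_pairs_b = obsB$n_pairs,
    r_a = obsA$r, r_b = obsB$r, t2 = t2_obs, p = p
  )
  new_sgs_result(out, "sgs_heterogeneity", meta = list(
    group_by = group_by, group_a = groups[1], group_b = groups[2],
    n_a = nA, n_b = nB,
    omega = omega, p_omega = p_omega, p_omega_chisq = p_omega_chisq,
    n_perm = n_perm, seed = if (is.null(seed)) NA_real_ else seed,
    permute_by = permute_by,
    bias_a = muA, bias_b = muB, var_a = vA, var_b = vB
  ))
}
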