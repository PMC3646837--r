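#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a correlogram
#'
#' @param x An `sgs_correlogram`.
#' @param ... Unused.
#' @return A plain tibble, one row per distance class, with a `midpoint`
#'   column added.
#' @method tidy sgs_correlogram
#' @export
tidy.sgs_correlogram <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(midpoint = (.data$class_lo + .data$class_hi) / 2, .after = "class_hi")
}

#' One-row summary of a correlogram's multiclass test
#'
#' @param x An `sgs_correlogram`.
#' @param ... Unused.
#' @return Tibble with `omega`, `p_omega`, `p_omega_chisq`, `n_perm`,
#'   `n_boot`, `n`, `seed`.
#' @method glance sgs_correlogram
#' @export
glance.sgs_correlogram <- function(x, ...) {
  m <- sgs_meta(x)
  tibble::tibble(omega = m$omega, p_omega = m$p_omega,
                 p_omega_chisq = m$p_omega_chisq,
                 n_perm = m$n_perm, n_boot = m$n_boot, n = m$n, seed = m$seed)
}

#' @rdname tidy.sgs_correlogram
#' @method tidy sgs_heterogeneity
#' @export
tidy.sgs_heterogeneity <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(midpoint = (.data$class_lo + .data$class_hi) / 2, .after = "class_hi")
}

#' One-row summary of a heterogeneity test
#'
#' @param x An `sgs_heterogeneity`.
#' @param ... Unused.
#' @return Tibble with the group labels, `omega`, `p_omega`,
#'   `p_omega_chisq`, `n_perm`, `seed`.
#' @method glance sgs_heterogeneity
#' @export
glance.sgs_heterogeneity <- function(x, ...) {
  m <- sgs_meta(x)
  tibble::tibble(group_a = m$group_a, group_b = m$group_b,
                 n_a = m$n_a, n_b = m$n_b,
                 omega = m$omega, p_omega = m$p_omega,
                 p_omega_chisq = m$p_omega_chisq,
                 n_perm = m$n_perm, seed = m$seed)
}

#' @rdname tidy.sgs_correlogram
#' @method tidy sgs_kinship_curve
#' @export
tidy.sgs_kinship_curve <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(midpoint = (.data$class_lo + .data$class_hi) / 2, .after = "class_hi")
}

#' One-row summary of a kinship curve
#'
#' @param x An `sgs_kinship_curve`.
#' @param ... Unused.
#' @return Tibble with `mode`, `focal_class`, `reference`, `n`, total
#'   `n_pairs`.
#' @method glance sgs_kinship_curve
#' @export
glance.sgs_kinship_curve <- function(x, ...) {
  m <- sgs_meta(x)
  tibble::tibble(mode = m$mode, focal_class = m$focal_class,
                 reference = m$reference, n = m$n, n_pairs = sum(x$n_pairs))
}

#' Correlogram figure
#'
#' Autocorrelation `r` against distance-class midpoint, with bootstrap error
#' bars and the dashed permutation null envelope around `r = 0`.
#'
#' @param object An `sgs_correlogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sgs_correlogram
#' @export
autoplot.sgs_correlogram <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$midpoint, y = .data$r)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$perm_lo), linetype = "dashed", na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$perm_hi), linetype = "dashed", na.rm = TRUE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$boot_lo, ymax = .data$boot_hi),
                           width = 0, na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "distance class midpoint (m)", y = "autocorrelation r") +
    ggplot2::theme_minimal()
}

#' Kinship-by-distance figure
#'
#' Mean Loiselle kinship per distance class, with the permutation envelope
#' when present.
#'
#' @param object An `sgs_kinship_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sgs_kinship_curve
#' @export
autoplot.sgs_kinship_curve <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$midpoint, y = .data$fij)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "distance class midpoint (m)", y = "mean kinship Fij") +
    ggplot2::theme_minimal()
  if (any(!is.na(df$perm_lo))) {
    p <- p +
      ggplot2::geom_line(ggplot2::aes(y = .data$perm_lo), linetype = "dashed", na.rm = TRUE) +
      ggplot2::geom_line(ggplot2::aes(y = .data$perm_hi), linetype = "dashed", na.rm = TRUE)
  }
  p
}

#' Heterogeneity figure
#'
#' The two groups' `r` profiles overlaid, with per-class significance stars
#' from the label-permutation test.
#'
#' @param object An `sgs_heterogeneity`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sgs_heterogeneity
#' @export
autoplot.sgs_heterogeneity <- function(object, ...) {
  m <- sgs_meta(object)
  df <- tidy(object) |>
    tidyr::pivot_longer(c("r_a", "r_b"), names_to = "group", values_to = "r") |>
    dplyr::mutate(group = ifelse(.data$group == "r_a", m$group_a, m$group_b))
  stars <- tidy(object) |> dplyr::filter(!is.na(.data$p), .data$p < 0.05)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$midpoint, y = .data$r,
                                        colour = .data$group)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "distance class midpoint (m)", y = "autocorrelation r",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (nrow(stars)) {
    p <- p + ggplot2::annotate("text", x = stars$midpoint,
                               y = max(df$r, na.rm = TRUE) * 1.1, label = "*")
  }
  p
}
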