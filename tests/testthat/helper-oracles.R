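# Fixture builders and independent brute-force oracles. The oracles are
# deliberately naive (explicit loops, scalar sums) and share no code with the
# implementation they check.

# Build an sgs_data tibble from a named list of loci, each an n x 2 matrix of
# allele codes (NA = missing).
toy_dataset <- function(loci, x, y, size_class = NULL, plot = "p1",
                        height_cm = NA_real_, clay_pct = NA_real_) {
  n <- length(x)
  geno <- tibble::tibble(id = paste0("i", seq_len(n)))
  for (l in names(loci)) {
    geno[[paste0(l, ".a1")]] <- loci[[l]][, 1]
    geno[[paste0(l, ".a2")]] <- loci[[l]][, 2]
  }
  meta <- tibble::tibble(id = geno$id, plot = plot, x = x, y = y,
                         height_cm = height_cm, clay_pct = clay_pct)
  if (!is.null(size_class)) meta$size_class <- size_class
  sgs_data(geno, meta)
}

# Random diploid dataset with uniform allele draws, coordinates in a box.
random_dataset <- function(n, n_loci = 2, n_alleles = 4, box = 100) {
  loci <- lapply(seq_len(n_loci), function(l) {
    matrix(sample.int(n_alleles, 2 * n, replace = TRUE) * 2L + 100L, n, 2)
  })
  names(loci) <- paste0("L", seq_len(n_loci))
  toy_dataset(loci, x = stats::runif(n, 0, box), y = stats::runif(n, 0, box))
}

# Half the squared Euclidean distance between allele-dosage vectors, one locus.
oracle_d2_locus <- function(g1, g2) {
  alleles <- sort(unique(c(g1, g2)))
  dose <- function(g) vapply(alleles, function(a) sum(g == a), numeric(1))
  0.5 * sum((dose(g1) - dose(g2))^2)
}

# Squared-distance matrix by per-pair scalar loops, with the missing-loci
# rescale rule.
oracle_distance_matrix <- function(data) {
  loci <- sgs_loci(data)
  n <- nrow(data)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    tot <- 0; complete <- 0
    for (l in loci) {
      gi <- c(data[[paste0(l, ".a1")]][i], data[[paste0(l, ".a2")]][i])
      gj <- c(data[[paste0(l, ".a1")]][j], data[[paste0(l, ".a2")]][j])
      if (anyNA(gi) || anyNA(gj)) next
      complete <- complete + 1
      tot <- tot + oracle_d2_locus(gi, gj)
    }
    D[i, j] <- tot * length(loci) / complete
  }
  D
}

# Gower double-centering by explicit scalar formula.
oracle_gower <- function(D) {
  n <- nrow(D)
  m <- mean(D)
  rm_ <- rowMeans(D)
  C <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    C[i, j] <- -0.5 * (D[i, j] - rm_[i] - rm_[j] + m)
  }
  C
}

# Loiselle kinship for one pair by direct scalar summation over loci and
# alleles, against a reference frequency table.
oracle_fij_pair <- function(data, i, j, reference) {
  loci <- sgs_loci(data)
  num <- 0; den <- 0
  for (l in loci) {
    gi <- c(data[[paste0(l, ".a1")]][i], data[[paste0(l, ".a2")]][i])
    gj <- c(data[[paste0(l, ".a1")]][j], data[[paste0(l, ".a2")]][j])
    if (anyNA(gi) || anyNA(gj)) next
    ref <- reference[reference$locus == l & !is.na(reference$allele), ]
    if (!nrow(ref)) next
    alleles <- sort(unique(c(ref$allele, gi, gj)))
    for (a in alleles) {
      p <- if (a %in% ref$allele) ref$freq[ref$allele == a] else 0
      qi <- sum(gi == a) / 2
      qj <- sum(gj == a) / 2
      num <- num + (qi - p) * (qj - p)
      if (ref$n_copies[1] > 1) num <- num + p * (1 - p) / (ref$n_copies[1] - 1)
      den <- den + p * (1 - p)
    }
  }
  num / den
}

# Observed per-class r with n_perm = n_boot = 0 (point estimates only).
point_correlogram <- function(data, edges) {
  spatial_autocorrelation(data, edges, n_perm = 0, n_boot = 0)
}
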