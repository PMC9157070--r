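# Between-cohort comparisons: hypergeometric overlap of significant-gene
# sets, the mean absolute difference of relative multiplicities with a
# fixed-margin contingency-table permutation null, and Skellam-based
# preferential enrichment.

#' Hypergeometric null for the overlap of two gene sets
#'
#' Two uniformly random subsets of sizes `|I1|` and `|I2|` drawn from
#' `N_genes` genes intersect in `K` genes, where `K` follows the
#' hypergeometric distribution.  Returns the exact null pmf and both tail
#' probabilities of the observed intersection: `P(K >= k)` supports
#' convergence (more shared enriched genes than chance), `P(K <= k)`
#' divergence.
#'
#' @param n1,n2 Sizes of the two significant-gene sets.
#' @param N_genes Genome-wide number of genes.
#' @param k Observed intersection size.
#' @param alpha Significance level used for the verdict (default 0.05).
#' @return An `overlap_test` with `pmf` (named by k over the support),
#'   `expected`, `p_convergence`, `p_divergence`, `call`.
#' @export
overlap_null <- function(n1, n2, N_genes, k, alpha = 0.05) {
  if (n1 > N_genes || n2 > N_genes) stopf("set sizes cannot exceed N_genes")
  support <- max(0, n1 + n2 - N_genes):min(n1, n2)
  if (!(k %in% support)) stopf("k = %d outside the overlap support [%d, %d]",
                               k, min(support), max(support))
  pmf <- stats::dhyper(support, n1, N_genes - n1, n2)
  names(pmf) <- support
  p_conv <- sum(pmf[support >= k])
  p_div <- sum(pmf[support <= k])
  verdict <- if (p_conv <= alpha) "convergent"
             else if (p_div <= alpha) "divergent"
             else "neither"
  structure(
    list(n1 = n1, n2 = n2, N_genes = N_genes, k = k, pmf = pmf,
         expected = n1 * n2 / N_genes,
         p_convergence = p_conv, p_divergence = p_div,
         alpha = alpha, call = verdict),
    class = "overlap_test"
  )
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("Gene-set overlap: |I1| = %d, |I2| = %d of %d genes; k = %d (expected %.2f)\n",
              x$n1, x$n2, x$N_genes, x$k, x$expected))
  cat(sprintf("  P(K >= k) = %.4g (convergence), P(K <= k) = %.4g (divergence): %s\n",
              x$p_convergence, x$p_divergence, x$call))
  invisible(x)
}

#' Relative multiplicities
#'
#' Normalizes a vector of multiplicities to sum to 1: `M_i = m_i / sum(m)`.
#'
#' @param m Nonnegative multiplicities with a positive sum.
#' @return The normalized vector.
#' @export
relative_multiplicities <- function(m) {
  s <- sum(m)
  if (s <= 0) stopf("multiplicities must have a positive sum")
  m / s
}

#' Mean absolute difference of relative multiplicities
#'
#' `<dM> = (1/|I|) sum_i |M_i1 - M_i2|` over a shared gene universe.  Both
#' vectors must be normalized over the same genes; the value is bounded by
#' `2/|I|`.
#'
#' @param M1,M2 Relative multiplicity vectors over the same gene universe.
#' @return The scalar mean absolute difference.
#' @export
mean_abs_diff <- function(M1, M2) {
  if (length(M1) != length(M2)) stopf("gene universes differ in size")
  if (!is.null(names(M1)) && !is.null(names(M2)) &&
      !identical(names(M1), names(M2))) {
    stopf("gene universes differ (names mismatch)")
  }
  mean(abs(M1 - M2))
}

#' Sample random contingency tables with fixed margins
#'
#' Draws uniform random nonnegative integer tables with the given row and
#' column sums via Patefield's algorithm (the standard fixed-margin
#' sampler), the permutation engine behind [fixed_margin_null()].
#'
#' @param n Number of tables.
#' @param row_margins,col_margins Margin totals (must agree in sum).
#' @param seed Optional RNG seed.
#' @return A list of `n` integer matrices.
#' @export
sample_fixed_margin_tables <- function(n, row_margins, col_margins,
                                       seed = NULL) {
  if (sum(row_margins) != sum(col_margins)) stopf("margins must agree in total")
  with_seed(seed, stats::r2dtable(n, row_margins, col_margins))
}

# <dM> from a gene x 2-cohort count matrix and per-gene lengths: relative
# multiplicities per column (m_i = n_i * Lbar/L_i; the Lbar factor cancels
# in the normalization).
dM_from_matrix <- function(tab, inv_len) {
  m1 <- tab[, 1] * inv_len
  m2 <- tab[, 2] * inv_len
  mean(abs(m1 / sum(m1) - m2 / sum(m2)))
}

#' Fixed-margin permutation null for divergence in multiplicity
#'
#' Standardizes the observed mean absolute difference of relative
#' multiplicities between two cohorts against a null in which mutation
#' counts are shuffled across a gene-by-cohort contingency table with both
#' margins held fixed (the total hits per gene and the total hits per
#' cohort).  Null tables are drawn uniformly with Patefield's algorithm
#' (`r2dtable`), the standard fixed-margin sampler.  Positive
#' `Z = (observed - null mean) / null sd` indicates divergence, negative
#' convergence.
#'
#' @param count_matrix Nonnegative integer matrix, genes (rows; the gene
#'   universe, typically the union of the cohorts' significant sets) by 2
#'   cohorts (columns).
#' @param lengths Optional effective gene lengths matching the rows
#'   (default: equal lengths, so multiplicities reduce to counts).
#' @param iterations Number of null tables (default 10000).
#' @param seed Optional RNG seed.
#' @return A `divergence_result` with `observed`, `null` (vector), `z`,
#'   `p_normal` (two-sided from Z), `p_empirical` (two-sided quantile),
#'   and the margins used.  A degenerate null (unique admissible table) has
#'   `z = NA` and is flagged.
#' @export
fixed_margin_null <- function(count_matrix, lengths = NULL,
                              iterations = 10000, seed = NULL) {
  count_matrix <- as.matrix(count_matrix)
  if (ncol(count_matrix) != 2) stopf("count_matrix must have exactly 2 cohorts")
  if (any(count_matrix < 0) || any(count_matrix != round(count_matrix))) {
    stopf("count_matrix must hold nonnegative integers")
  }
  col_tot <- colSums(count_matrix)
  if (any(col_tot == 0)) stopf("degenerate margins: a cohort has no mutations")
  row_tot <- rowSums(count_matrix)
  lengths <- lengths %||% rep(1, nrow(count_matrix))
  if (length(lengths) != nrow(count_matrix)) {
    stopf("lengths must match the rows of count_matrix")
  }
  inv_len <- 1 / lengths
  observed <- dM_from_matrix(count_matrix, inv_len)
  with_seed(seed, {
    tabs <- sample_fixed_margin_tables(iterations, row_tot, col_tot)
    null <- vapply(tabs, dM_from_matrix, numeric(1), inv_len = inv_len)
    mu <- mean(null); sdev <- stats::sd(null)
    degenerate <- !is.finite(sdev) || sdev == 0
    z <- if (degenerate) NA_real_ else (observed - mu) / sdev
    if (degenerate) warnf("null distribution is degenerate; Z undefined")
    p_emp <- (sum(abs(null - mu) >= abs(observed - mu)) + 1) / (iterations + 1)
    structure(
      list(observed = observed, null = null, null_mean = mu, null_sd = sdev,
           z = z,
           p_normal = if (degenerate) NA_real_ else
             2 * stats::pnorm(-abs(z)),
           p_empirical = p_emp,
           row_margins = row_tot, col_margins = col_tot,
           iterations = iterations),
      class = "divergence_result"
    )
  })
}

#' @export
print.divergence_result <- function(x, ...) {
  cat(sprintf("Fixed-margin divergence test over %d genes, %d null tables\n",
              length(x$row_margins), x$iterations))
  cat(sprintf("  observed <dM> = %.5g; null %.5g +/- %.5g\n",
              x$observed, x$null_mean, x$null_sd))
  if (is.na(x$z)) {
    cat("  Z undefined (degenerate null)\n")
  } else {
    cat(sprintf("  Z = %.3f (%s); p = %.4g (normal), %.4g (empirical)\n",
                x$z, if (x$z > 0) "divergence" else "convergence",
                x$p_normal, x$p_empirical))
  }
  invisible(x)
}

#' Skellam probability mass function
#'
#' The distribution of the difference `N1 - N2` of two independent Poisson
#' counts with rates `mu1`, `mu2`, evaluated stably in log space with
#' exponentially scaled Bessel functions.
#'
#' @param k Integer difference value(s).
#' @param mu1,mu2 Positive Poisson rates.
#' @return `P(N1 - N2 = k)`.
#' @export
dskellam <- function(k, mu1, mu2) {
  if (mu1 <= 0 || mu2 <= 0) stopf("rates must be positive")
  x <- 2 * sqrt(mu1 * mu2)
  lp <- -(mu1 + mu2) + (k / 2) * (log(mu1) - log(mu2)) +
    log(besselI(x, abs(k), expon.scaled = TRUE)) + x
  exp(lp)
}

#' Skellam test for preferential enrichment
#'
#' Two-sided tail probability that two independent Poisson counts differ at
#' least as much as observed: `P(|N1 - N2| >= |n1 - n2|)` under rates
#' `(mu1, mu2)`.  Used per gene to flag preferential enrichment of one
#' cohort over the other; rates default to the gene's expected counts under
#' each cohort's total and the gene's length share.
#'
#' @param n1,n2 Observed counts in the two cohorts.
#' @param mu1,mu2 Null Poisson rates.
#' @return The two-sided p-value (1 when `n1 = n2`).
#' @export
skellam_preferential <- function(n1, n2, mu1, mu2) {
  d <- abs(n1 - n2)
  if (d == 0) return(1)
  # sum the interior |k| < d and complement; the interior is a short sum
  inner <- sum(dskellam((-d + 1):(d - 1), mu1, mu2))
  max(0, min(1, 1 - inner))
}

#' Per-gene Skellam preferential-enrichment scan
#'
#' Applies [skellam_preferential()] to every gene of two cohorts, with null
#' rates `mu_ci = n_tot_c * L_i / (Lbar * N_genes)` (each cohort's expected
#' count for the gene), and controls the false discovery rate with the same
#' survival-curve rule as the Poisson enrichment scan: `P*` is the largest
#' observed p-value at which the expected number of null genes reaching it,
#' over the observed number, stays below `alpha`.
#'
#' @param counts1,counts2 Named per-gene count vectors for the two cohorts.
#' @param catalog A [gene_catalog()].
#' @param alpha Target false discovery rate (default 0.05).
#' @return A data frame with `gene_id`, `n1`, `n2`, `mu1`, `mu2`, `p_value`,
#'   `significant`, plus attributes `p_star` and `alpha`.
#' @export
skellam_gene_scan <- function(counts1, counts2, catalog, alpha = 0.05) {
  full1 <- stats::setNames(numeric(nrow(catalog)), catalog$gene_id)
  full2 <- full1
  full1[names(counts1)] <- counts1
  full2[names(counts2)] <- counts2
  Lbar <- attr(catalog, "Lbar")
  N <- nrow(catalog)
  mu1 <- poisson_null_rate(sum(full1), catalog$length, Lbar, N)
  mu2 <- poisson_null_rate(sum(full2), catalog$length, Lbar, N)
  p <- mapply(skellam_preferential, full1, full2, mu1, mu2)
  # survival-curve FDR over the Skellam nulls: find, per candidate P, the
  # smallest |difference| with tail <= P and its null probability
  cand <- sort(unique(p[p < 1]), decreasing = TRUE)
  # per gene, the decreasing sequence of attainable two-sided tails at
  # |difference| = 1, 2, ... (cached once; reused across candidate P)
  tails <- lapply(seq_len(N), function(i) {
    v <- numeric(0)
    d <- 1
    repeat {
      t <- skellam_preferential(d, 0, mu1[i], mu2[i])
      v <- c(v, t)
      if (t < 1e-15 || d >= 500) break
      d <- d + 1
    }
    v
  })
  p_star <- 0
  for (P in cand) {
    observed <- sum(p <= P)
    expected <- sum(vapply(tails, function(v) {
      hit <- which(v <= P)
      if (length(hit)) v[hit[1]] else 0
    }, numeric(1)))
    if (expected / observed <= alpha) {
      p_star <- P
      break
    }
  }
  out <- data.frame(gene_id = catalog$gene_id, n1 = as.numeric(full1),
                    n2 = as.numeric(full2), mu1 = mu1, mu2 = mu2,
                    p_value = p, significant = p <= p_star & p < 1,
                    stringsAsFactors = FALSE)
  attr(out, "p_star") <- p_star
  attr(out, "alpha") <- alpha
  out
}
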