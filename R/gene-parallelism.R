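# Gene-level parallelism: multiplicity, the genome-wide log-likelihood excess
# of the gene-specific model over the uniform null, per-gene Poisson
# enrichment P-values, and a survival-curve false-discovery threshold.

#' Build a gene catalog
#'
#' A catalog of genes with their effective nonsynonymous lengths `L_i` and
#' optional named gene-set memberships (e.g. a regulon).
#'
#' @param gene_id Character vector of gene identifiers.
#' @param length Effective nonsynonymous lengths `L_i` (> 0), parallel to
#'   `gene_id`.
#' @param sets Optional named list of character vectors of gene ids.
#' @return A `gene_catalog` data frame with attributes `Lbar` (mean length)
#'   and `sets`.
#' @export
gene_catalog <- function(gene_id, length, sets = list()) {
  if (base::length(gene_id) != base::length(length)) {
    stopf("gene_id and length must be parallel")
  }
  if (anyDuplicated(gene_id)) stopf("duplicated gene ids in catalog")
  if (any(length <= 0)) stopf("gene lengths must be > 0")
  for (nm in names(sets)) {
    extra <- setdiff(sets[[nm]], gene_id)
    if (base::length(extra)) {
      stopf("gene set '%s' names unknown gene(s): %s", nm,
            paste(utils::head(extra, 3), collapse = ", "))
    }
  }
  out <- data.frame(gene_id = as.character(gene_id), length = as.numeric(length),
                    stringsAsFactors = FALSE)
  attr(out, "Lbar") <- mean(out$length)
  attr(out, "sets") <- sets
  class(out) <- c("gene_catalog", "data.frame")
  out
}

#' Gene multiplicity
#'
#' The mutation count of a gene rescaled by the ratio of the mean effective
#' length to the gene's own: `m_i = n_i * Lbar / L_i`.  Values above 1 mark
#' an excess of hits relative to a size-proportional null.
#'
#' @param n_i Mutation count(s).
#' @param L_i Effective gene length(s) (> 0).
#' @param Lbar Mean effective length over all genes.
#' @return Multiplicities, vectorized over the inputs.
#' @export
multiplicity <- function(n_i, L_i, Lbar) {
  if (any(L_i <= 0)) stopf("L_i must be > 0")
  n_i * Lbar / L_i
}

#' Genome-wide parallelism score (log-likelihood excess)
#'
#' The net log-likelihood gain of gene-specific multiplicities over the
#' uniform-multiplicity null: `delta_ell = sum_i n_i log(m_i / mbar)` with
#' `mbar = n_tot / N_genes`, summing over genes with `n_i > 0` (a gene with
#' no hits contributes 0, the `n log n -> 0` limit).  Natural logarithms.
#' The statistic equals `n_tot` times a Kullback-Leibler divergence and is
#' therefore nonnegative, vanishing only when counts are exactly
#' proportional to lengths.
#'
#' @param counts Named numeric vector of per-gene mutation counts; names are
#'   gene ids present in `catalog`.  Genes absent from `counts` are taken as
#'   zero.
#' @param catalog A [gene_catalog()].
#' @return The scalar score.
#' @export
delta_ell <- function(counts, catalog) {
  counts <- counts[counts > 0]
  n_tot <- sum(counts)
  if (n_tot == 0) return(0)
  idx <- match(names(counts), catalog$gene_id)
  if (anyNA(idx)) {
    stopf("counts name gene(s) missing from the catalog: %s",
          paste(utils::head(names(counts)[is.na(idx)], 3), collapse = ", "))
  }
  Lbar <- attr(catalog, "Lbar")
  m <- multiplicity(counts, catalog$length[idx], Lbar)
  mbar <- n_tot / nrow(catalog)
  sum(counts * log(m / mbar))
}

#' Permutation significance for the parallelism score
#'
#' Reassigns the observed mutations to genes with probability proportional
#' to `L_i` and recomputes the score, giving a null distribution and a
#' one-sided p-value for the observed value.
#'
#' @inheritParams delta_ell
#' @param iterations Number of permutations (default 10000).
#' @param seed Optional RNG seed.
#' @return A list with `observed`, `null` (vector), `p_value`.
#' @export
delta_ell_permutation <- function(counts, catalog, iterations = 10000,
                                  seed = NULL) {
  obs <- delta_ell(counts, catalog)
  n_tot <- sum(counts)
  prob <- catalog$length / sum(catalog$length)
  with_seed(seed, {
    null <- vapply(seq_len(iterations), function(i) {
      perm <- stats::rmultinom(1, n_tot, prob)[, 1]
      names(perm) <- catalog$gene_id
      delta_ell(perm, catalog)
    }, numeric(1))
    list(observed = obs, null = null,
         p_value = (sum(null >= obs) + 1) / (iterations + 1))
  })
}

#' Subsampled parallelism-score distribution
#'
#' Draws `target_total` mutations without replacement from the observed
#' multiset of mutations (each observed mutation equally likely) and
#' recomputes the parallelism score, controlling for differences in total
#' mutation count between cohorts.  A named gene set can be excluded first
#' (e.g. a regulon-exclusion control).
#'
#' @inheritParams delta_ell
#' @param target_total Number of mutations per subsample (must not exceed
#'   the observed total after any exclusion).
#' @param iterations Number of subsamples (default 1000).
#' @param exclude_set Optional name of a catalog gene set to drop before
#'   subsampling.
#' @param seed Optional RNG seed.
#' @return Numeric vector of scores, one per iteration.
#' @export
subsample_delta_ell <- function(counts, catalog, target_total,
                                iterations = 1000, exclude_set = NULL,
                                seed = NULL) {
  if (target_total <= 0) stopf("target_total must be positive")
  if (!is.null(exclude_set)) {
    sets <- attr(catalog, "sets")
    if (is.null(sets[[exclude_set]])) stopf("unknown gene set '%s'", exclude_set)
    counts <- counts[!(names(counts) %in% sets[[exclude_set]])]
  }
  counts <- counts[counts > 0]
  n_tot <- sum(counts)
  if (target_total > n_tot) stopf("target_total exceeds the observed total")
  genes <- rep(names(counts), counts)
  with_seed(seed, {
    vapply(seq_len(iterations), function(i) {
      sub <- sample(genes, target_total)
      tab <- table(sub)
      delta_ell(stats::setNames(as.numeric(tab), names(tab)), catalog)
    }, numeric(1))
  })
}

# Null Poisson rate of gene i: expected count under a size-proportional
# assignment of n_tot mutations.
poisson_null_rate <- function(n_tot, L_i, Lbar, N_genes) {
  n_tot * L_i / (Lbar * N_genes)
}

#' Poisson enrichment P-value for a gene
#'
#' The upper-tail Poisson probability `P_i = P(N >= n_i)` under the
#' size-proportional null rate `lambda = n_tot L_i / (Lbar N_genes)`,
#' evaluated through the upper regularized incomplete gamma function
#' (`ppois(..., lower.tail = FALSE)`) for numerical stability.
#'
#' @param n_i Observed count(s).
#' @param n_tot Total mutations in the cohort.
#' @param L_i Effective gene length(s).
#' @param Lbar Mean effective length.
#' @param N_genes Number of genes in the genome.
#' @return P-value(s) in `(0, 1]`.
#' @export
poisson_gene_pvalue <- function(n_i, n_tot, L_i, Lbar, N_genes) {
  lambda <- poisson_null_rate(n_tot, L_i, Lbar, N_genes)
  stats::ppois(n_i - 1, lambda, lower.tail = FALSE)
}

#' Survival-curve critical P-value
#'
#' The false-discovery threshold `P*`: the largest observed P-value `P` such
#' that the expected number of null genes reaching `P_i <= P` (from the
#' Poisson survival curves, restricted to genes passing the count filter),
#' divided by the observed number reaching it, is at most `alpha`.  Returns
#' 0 when no threshold qualifies, so no gene is called.
#'
#' @param pvalues Observed per-gene P-values (genes passing the count
#'   filter).
#' @param lambda Per-gene null Poisson rates for **all** genes in the genome.
#' @param alpha Target false discovery rate (default 0.05).
#' @param count_filter Minimum mutation count for a gene to be eligible
#'   (default 3); the same filter is applied inside the null expectation.
#' @return The critical threshold `P*` (0 if none qualifies).
#' @export
critical_pvalue <- function(pvalues, lambda, alpha = 0.05, count_filter = 3) {
  if (!length(pvalues)) stopf("no observed P-values supplied")
  cand <- sort(unique(pvalues), decreasing = TRUE)
  for (P in cand) {
    observed <- sum(pvalues <= P)
    # smallest count whose Poisson tail is <= P, per gene; upper-tail
    # quantile keeps precision for tiny P, with a one-step correction
    nstar <- stats::qpois(P, lambda, lower.tail = FALSE) + 1
    lo <- stats::ppois(nstar - 2, lambda, lower.tail = FALSE) <= P & nstar >= 2
    nstar[lo] <- nstar[lo] - 1
    hi <- stats::ppois(nstar - 1, lambda, lower.tail = FALSE) > P
    nstar[hi] <- nstar[hi] + 1
    nmin <- pmax(count_filter, nstar)
    expected <- sum(stats::ppois(nmin - 1, lambda, lower.tail = FALSE))
    if (expected / observed <= alpha) return(P)
  }
  0
}

#' Gene-level enrichment analysis
#'
#' Runs the full parallelism pipeline on one cohort (strain-transfer
#' combination): multiplicities, the genome-wide parallelism score, per-gene
#' Poisson P-values, the survival-curve critical threshold (or plain
#' Benjamini-Hochberg), and the significant gene set.  Only genes with at
#' least `count_filter` mutations are eligible for significance; all
#' mutations still contribute to the total used for the null rates.
#'
#' @param counts Named numeric vector of per-gene nonsynonymous mutation
#'   counts, pooled across replicate populations.
#' @param catalog A [gene_catalog()].
#' @param alpha Target false discovery rate (default 0.05).
#' @param count_filter Minimum per-gene count for significance testing
#'   (default 3).
#' @param method `"survival"` (default; survival-curve `P*`) or `"BH"`.
#' @return An `enrichment_result` with per-gene table `genes` (`gene_id`,
#'   `n`, `length`, `multiplicity`, `p_value`), `delta_ell`, `m_bar`,
#'   `p_star`, `significant` (gene ids), `alpha`, `count_filter`, `n_tot`.
#' @export
gene_enrichment <- function(counts, catalog, alpha = 0.05, count_filter = 3,
                            method = c("survival", "BH")) {
  method <- match.arg(method)
  full <- stats::setNames(numeric(nrow(catalog)), catalog$gene_id)
  idx <- match(names(counts), catalog$gene_id)
  if (anyNA(idx)) {
    stopf("counts name gene(s) missing from the catalog: %s",
          paste(utils::head(names(counts)[is.na(idx)], 3), collapse = ", "))
  }
  full[idx] <- counts
  n_tot <- sum(full)
  Lbar <- attr(catalog, "Lbar")
  N <- nrow(catalog)
  lambda <- poisson_null_rate(n_tot, catalog$length, Lbar, N)
  genes <- data.frame(
    gene_id = catalog$gene_id, n = as.numeric(full),
    length = catalog$length,
    multiplicity = multiplicity(full, catalog$length, Lbar),
    p_value = poisson_gene_pvalue(full, n_tot, catalog$length, Lbar, N),
    stringsAsFactors = FALSE
  )
  eligible <- genes$n >= count_filter
  if (method == "survival") {
    p_star <- if (any(eligible)) {
      critical_pvalue(genes$p_value[eligible], lambda, alpha, count_filter)
    } else 0
    sig <- genes$gene_id[eligible & genes$p_value <= p_star]
  } else {
    p_adj <- rep(NA_real_, N)
    p_adj[eligible] <- stats::p.adjust(genes$p_value[eligible], method = "BH")
    genes$p_adjusted <- p_adj
    sig <- genes$gene_id[eligible & !is.na(p_adj) & p_adj <= alpha]
    p_star <- if (length(sig)) max(genes$p_value[genes$gene_id %in% sig]) else 0
  }
  structure(
    list(genes = genes, delta_ell = delta_ell(full, catalog),
         m_bar = n_tot / N, p_star = p_star, significant = sig,
         alpha = alpha, count_filter = count_filter, n_tot = n_tot,
         method = method),
    class = "enrichment_result"
  )
}

#' Significant gene set of an enrichment result
#'
#' `I = {i : P_i <= P*, n_i >= count_filter}`.
#'
#' @param result An [gene_enrichment()] result.
#' @return Character vector of significant gene ids.
#' @export
significant_genes <- function(result) {
  stopifnot(inherits(result, "enrichment_result"))
  result$significant
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Gene-level parallelism\n")
  cat(sprintf("  %d genes, %g mutations; delta_ell = %.3f (mbar = %.4g)\n",
              nrow(x$genes), x$n_tot, x$delta_ell, x$m_bar))
  cat(sprintf("  P* = %.3g (alpha = %g, count filter >= %d, %s rule): %d significant gene(s)\n",
              x$p_star, x$alpha, x$count_filter,
              if (x$method == "survival") "survival-curve" else "BH",
              length(x$significant)))
  if (length(x$significant)) {
    cat("  ", paste(utils::head(x$significant, 10), collapse = ", "),
        if (length(x$significant) > 10) "..." else "", "\n")
  }
  invisible(x)
}

#' Binomial region/gene-set enrichment test
#'
#' Upper-tail binomial test of whether a region (or gene set) occupying a
#' fraction `l` of the genome acquired at least the observed number of
#' mutations: `p = P(N >= n_region)` with `N ~ Binomial(n_total, l)`.
#'
#' @param n_region Mutations observed in the region.
#' @param n_total Total mutations observed.
#' @param l Fraction of the genome occupied by the region, in (0, 1).
#' @return The upper-tail p-value.
#' @export
region_binomial_test <- function(n_region, n_total, l) {
  if (l <= 0 || l >= 1) stopf("l must be in (0, 1)")
  if (n_region > n_total) stopf("n_region cannot exceed n_total")
  stats::pbinom(n_region - 1, n_total, l, lower.tail = FALSE)
}

#' Signed between-cohort region-fraction difference test
#'
#' Compares the fraction of mutations falling in a region between two
#' cohorts against a simulated binomial null in which both cohorts draw
#' their region counts at rate `l`.  The two-sided p-value is the fraction
#' of simulated |difference| values at least as large as observed.
#'
#' @param n_region_1,n_total_1 Region and total counts of cohort 1.
#' @param n_region_2,n_total_2 Region and total counts of cohort 2.
#' @param l Genome fraction of the region.
#' @param iterations Simulated null draws (default 10000).
#' @param seed Optional RNG seed.
#' @return A list with `observed_diff` (cohort1 - cohort2 fractions),
#'   `p_value`.
#' @export
region_fraction_difference <- function(n_region_1, n_total_1,
                                       n_region_2, n_total_2, l,
                                       iterations = 10000, seed = NULL) {
  if (l <= 0 || l >= 1) stopf("l must be in (0, 1)")
  obs <- n_region_1 / n_total_1 - n_region_2 / n_total_2
  with_seed(seed, {
    d1 <- stats::rbinom(iterations, n_total_1, l) / n_total_1
    d2 <- stats::rbinom(iterations, n_total_2, l) / n_total_2
    null <- d1 - d2
    list(observed_diff = obs,
         p_value = (sum(abs(null) >= abs(obs)) + 1) / (iterations + 1))
  })
}
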