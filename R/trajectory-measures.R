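# Trajectory-level summary measures and their distributional comparisons.

#' Per-mutation trajectory measures
#'
#' Computes, for each mutation in each population:
#' * `f_max`: the maximum estimated frequency over the first `t_max_points`
#'   observations (default 6, matching truncation to the shortest shared
#'   sampling series);
#' * `|df|/dtau`: the per-generation magnitude of frequency change between
#'   every pair of consecutive observations with both frequencies present;
#' * the direction ratio `f(tau + dtau) / f(tau)` for those same intervals,
#'   computed only where `f(tau) > 0` (a ratio of 0 is retained when the
#'   later frequency is 0).
#'
#' @param traj A [trajectory_matrix()] with estimated frequencies.
#' @param t_max_points Number of leading observations used for `f_max`
#'   (default 6); `Inf` uses all.
#' @return A `trajectory_measures` object: a list with data frames `fmax`
#'   (mutation_id, population_id, strain, regime, f_max) and `intervals`
#'   (one row per consecutive observation pair: rate `abs_df_dtau` and
#'   `direction_ratio`, `NA` where undefined).
#' @export
trajectory_measures <- function(traj, t_max_points = 6) {
  if (is.null(traj$freq)) traj <- estimate_frequencies(traj)
  traj <- traj[order(traj$population_id, traj$mutation_id, traj$day), ]
  key <- interaction(traj$population_id, traj$mutation_id, drop = TRUE)
  groups <- split(traj, key)

  fmax_rows <- lapply(groups, function(g) {
    f <- g$freq[!is.na(g$freq)]
    n <- min(length(f), t_max_points)
    if (n == 0) return(NULL)
    data.frame(mutation_id = g$mutation_id[1], population_id = g$population_id[1],
               strain = g$strain[1], regime = g$regime[1],
               f_max = max(f[seq_len(n)]), stringsAsFactors = FALSE)
  })
  int_rows <- lapply(groups, function(g) {
    ok <- !is.na(g$freq)
    g <- g[ok, , drop = FALSE]
    if (nrow(g) < 2) return(NULL)
    f0 <- g$freq[-nrow(g)]; f1 <- g$freq[-1]
    dtau <- diff(g$generations)
    ratio <- ifelse(f0 > 0, f1 / f0, NA_real_)
    data.frame(mutation_id = g$mutation_id[1], population_id = g$population_id[1],
               strain = g$strain[1], regime = g$regime[1],
               tau = g$generations[-nrow(g)], dtau = dtau,
               abs_df_dtau = abs(f1 - f0) / dtau,
               direction_ratio = ratio, stringsAsFactors = FALSE)
  })
  structure(
    list(fmax = do.call(rbind, fmax_rows) %||% data.frame(),
         intervals = do.call(rbind, int_rows) %||% data.frame(),
         t_max_points = t_max_points),
    class = "trajectory_measures"
  )
}

#' @export
print.trajectory_measures <- function(x, ...) {
  cat(sprintf("Trajectory measures: %d mutations, %d intervals (f_max over first %s points)\n",
              nrow(x$fmax), nrow(x$intervals), format(x$t_max_points)))
  invisible(x)
}

#' Empirical survival distribution
#'
#' The complement of the empirical cumulative distribution function:
#' `S(x) =` fraction of values strictly greater than `x`, so `S` is 1 below
#' the minimum and 0 at (and above) the maximum.
#'
#' @param values Numeric vector with at least one finite value.
#' @return A `survival_curve` object; evaluate it with
#'   [survival_prob()] or plot it.
#' @export
survival_distribution <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) stopf("no finite values supplied")
  structure(list(values = sort(values), n = length(values)),
            class = "survival_curve")
}

#' Evaluate a survival curve
#'
#' @param curve A [survival_distribution()] object.
#' @param x Points at which to evaluate `S(x) = P(value > x)`.
#' @return Numeric vector of survival probabilities.
#' @export
survival_prob <- function(curve, x) {
  stopifnot(inherits(curve, "survival_curve"))
  vapply(x, function(xi) mean(curve$values > xi), numeric(1))
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("Empirical survival distribution of %d values (median %.4g)\n",
              x$n, stats::median(x$values)))
  invisible(x)
}

#' @export
plot.survival_curve <- function(x, log = "", ...) {
  xs <- x$values
  graphics::plot(xs, survival_prob(x, xs), type = "s", xlab = "value",
                 ylab = "fraction > value", log = log, ...)
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Computes the two-sample KS statistic `D = sup |ECDF_a - ECDF_b|` and its
#' asymptotic p-value.
#'
#' @param sample_a,sample_b Nonempty numeric vectors.
#' @return A list with `D` and `p_value`.
#' @seealso [ks_compare_batch()] for a set of comparisons with
#'   Benjamini-Hochberg correction.
#' @export
ks_compare <- function(sample_a, sample_b) {
  sample_a <- sample_a[is.finite(sample_a)]
  sample_b <- sample_b[is.finite(sample_b)]
  if (!length(sample_a) || !length(sample_b)) stopf("both samples must be nonempty")
  ans <- suppressWarnings(stats::ks.test(sample_a, sample_b, exact = FALSE))
  list(D = unname(ans$statistic), p_value = unname(ans$p.value))
}

#' Batch KS comparisons with Benjamini-Hochberg correction
#'
#' Applies [ks_compare()] to each named pair of samples and adjusts the
#' p-values across the batch with the Benjamini-Hochberg step-up procedure.
#'
#' @param pairs A named list; each element is a list of two numeric vectors.
#' @param alpha Significance level applied to the adjusted p-values.
#' @return A data frame with `comparison`, `D`, `p_value`, `p_adjusted`,
#'   `significant`.
#' @export
ks_compare_batch <- function(pairs, alpha = 0.05) {
  res <- lapply(pairs, function(pr) ks_compare(pr[[1]], pr[[2]]))
  p <- vapply(res, `[[`, numeric(1), "p_value")
  data.frame(
    comparison = names(pairs) %||% as.character(seq_along(pairs)),
    D = vapply(res, `[[`, numeric(1), "D"),
    p_value = p,
    p_adjusted = stats::p.adjust(p, method = "BH"),
    significant = stats::p.adjust(p, method = "BH") < alpha,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Threshold-based mutation fate classification
#'
#' A transparent rule replacing model-based fate inference: a mutation is
#' `"fixed"` if its final observed frequency is at least `fix_threshold`;
#' `"extinct"` if it was ever detected (frequency at least
#' `detect_threshold`) and its final observed frequency is at most
#' `extinct_threshold`; otherwise `"segregating"`.  Externally produced fate
#' labels can be used anywhere this function's output is accepted.
#'
#' @param trajectory Numeric vector of observed frequencies (NAs dropped).
#' @param detect_threshold Detection floor (default 0.05).
#' @param fix_threshold Fixation threshold (default 0.95).
#' @param extinct_threshold Extinction threshold (default 0.01).
#' @return One of `"segregating"`, `"fixed"`, `"extinct"`.
#' @export
classify_fate <- function(trajectory, detect_threshold = 0.05,
                          fix_threshold = 0.95, extinct_threshold = 0.01) {
  trajectory <- trajectory[!is.na(trajectory)]
  if (!length(trajectory)) stopf("empty trajectory")
  if (!(0 < extinct_threshold && extinct_threshold < detect_threshold &&
        detect_threshold < fix_threshold && fix_threshold < 1)) {
    stopf("thresholds must satisfy 0 < extinct < detect < fix < 1")
  }
  final <- trajectory[length(trajectory)]
  if (final >= fix_threshold) return("fixed")
  if (max(trajectory) >= detect_threshold && final <= extinct_threshold) {
    return("extinct")
  }
  "segregating"
}

#' Probability of extinction given detection
#'
#' The number of detected mutations classified extinct divided by the total
#' number of detected mutations.
#'
#' @param fates Character vector of fates for the detected mutations
#'   (e.g. from [classify_fate()]).
#' @return A probability in `[0, 1]`.
#' @export
prob_extinct_given_detected <- function(fates) {
  if (!length(fates)) stopf("no detected mutations")
  mean(fates == "extinct")
}

#' Pairwise correlations of simultaneously segregating mutations
#'
#' For every pair of mutations within a population that are simultaneously
#' segregating (both frequencies strictly in (0, 1)) at `min_shared` or more
#' timepoints, computes the Pearson correlation over those shared
#' timepoints.  Pairs with zero variance in the shared window are skipped
#' with a message.  Both `r` and `r^2` are returned; the squared coefficient
#' is the conventional recombination-rate proxy.
#'
#' @param traj A [trajectory_matrix()] with estimated frequencies.
#' @param min_shared Minimum number of shared segregating timepoints
#'   (default 3).
#' @return A data frame with `population_id`, `mutation_a`, `mutation_b`,
#'   `n_shared`, `r`, `r_squared`.
#' @export
pairwise_trajectory_correlation <- function(traj, min_shared = 3) {
  if (is.null(traj$freq)) traj <- estimate_frequencies(traj)
  out <- list()
  skipped <- 0L
  for (pop in unique(traj$population_id)) {
    sub <- traj[traj$population_id == pop, ]
    wide <- stats::reshape(
      sub[, c("mutation_id", "day", "freq")],
      idvar = "mutation_id", timevar = "day", direction = "wide"
    )
    ids <- wide$mutation_id
    m <- as.matrix(wide[, -1, drop = FALSE])
    seg <- is.finite(m) & m > 0 & m < 1
    n <- nrow(m)
    if (n < 2) next
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        shared <- which(seg[i, ] & seg[j, ])
        if (length(shared) < min_shared) next
        xi <- m[i, shared]; xj <- m[j, shared]
        if (stats::sd(xi) == 0 || stats::sd(xj) == 0) {
          skipped <- skipped + 1L
          next
        }
        r <- stats::cor(xi, xj)
        out[[length(out) + 1L]] <- data.frame(
          population_id = pop, mutation_a = ids[i], mutation_b = ids[j],
          n_shared = length(shared), r = r, r_squared = r^2,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (skipped > 0) message(sprintf("skipped %d zero-variance pair(s)", skipped))
  do.call(rbind, out) %||%
    data.frame(population_id = character(0), mutation_a = character(0),
               mutation_b = character(0), n_shared = integer(0),
               r = numeric(0), r_squared = numeric(0))
}

#' Site-weighted pN/pS ratio
#'
#' The ratio of nonsynonymous to synonymous polymorphism counts, weighted by
#' the genomic fractions of each site class:
#' `(n_nonsyn / n_syn) * (syn_site_fraction / nonsyn_site_fraction)`.
#' Equals 1 when counts are proportional to site availability.
#'
#' @param n_nonsyn,n_syn Observed mutation counts in each class.
#' @param nonsyn_site_fraction,syn_site_fraction Fractions of genomic coding
#'   sites in each class (positive, summing to at most 1).
#' @return The weighted ratio; `NA` with a warning when `n_syn = 0`.
#' @export
pn_ps <- function(n_nonsyn, n_syn, nonsyn_site_fraction, syn_site_fraction) {
  if (nonsyn_site_fraction <= 0 || syn_site_fraction <= 0 ||
      nonsyn_site_fraction + syn_site_fraction > 1 + 1e-12) {
    stopf("site fractions must be positive and sum to at most 1")
  }
  if (n_syn == 0) {
    warnf("pN/pS undefined with zero synonymous mutations")
    return(NA_real_)
  }
  (n_nonsyn / n_syn) * (syn_site_fraction / nonsyn_site_fraction)
}

#' Generations per transfer from population sizes
#'
#' Under serial batch transfer, generations accrue mostly during exponential
#' growth, so the per-transfer generation count is the binary logarithm of
#' the final-to-initial size ratio: `dtau = log2(Nf / Ni)`, and the total over
#' an experiment is `tau = dtau * n_transfers`.  Vector inputs are treated as
#' per-replicate estimates and averaged on the log2 scale, with a standard
#' error.
#'
#' @param N_f,N_i Final and initial population sizes (CFU-scale counts; > 0).
#' @param n_transfers Number of transfer cycles (default 1).
#' @return A `generation_estimate` list: `delta_tau`, `se`,
#'   `total_generations`, `n_transfers`, `ratio`.
#' @examples
#' estimate_generations(10, 1, n_transfers = 700) # 1:10 dilution, 700 cycles
#' @export
estimate_generations <- function(N_f, N_i, n_transfers = 1) {
  if (any(N_f <= 0) || any(N_i <= 0)) stopf("population sizes must be > 0")
  per_rep <- log2(N_f / N_i)
  dtau <- mean(per_rep)
  se <- if (length(per_rep) > 1) stats::sd(per_rep) / sqrt(length(per_rep)) else NA_real_
  structure(
    list(delta_tau = dtau, se = se,
         total_generations = dtau * n_transfers,
         n_transfers = n_transfers, ratio = mean(N_f / N_i)),
    class = "generation_estimate"
  )
}

#' @export
print.generation_estimate <- function(x, ...) {
  cat(sprintf("Generations per transfer: %.3f%s; total over %d transfers: %.1f\n",
              x$delta_tau,
              if (is.na(x$se)) "" else sprintf(" +/- %.3f (SE)", x$se),
              x$n_transfers, x$total_generations))
  invisible(x)
}

#' Relative log fitness from strain counts
#'
#' The relative log fitness of a mutant against a reference after time `t`:
#' `X(t) = log[(N_mut(t) / N_wt(t)) * (N_wt(0) / N_mut(0))]`.  The natural
#' logarithm is the default, the standard convention for selection-like
#' quantities; `base` overrides it.
#'
#' @param counts_mut_t,counts_wt_t Counts of the two strains at time `t`.
#' @param counts_mut_0,counts_wt_0 Counts at time 0.
#' @param base Logarithm base (default `exp(1)`).
#' @return `X(t)`; `NA` with a warning on any zero count.
#' @export
relative_log_fitness <- function(counts_mut_t, counts_wt_t,
                                 counts_mut_0, counts_wt_0, base = exp(1)) {
  cnt <- c(counts_mut_t, counts_wt_t, counts_mut_0, counts_wt_0)
  if (any(cnt <= 0)) {
    warnf("relative log fitness undefined with zero counts")
    return(NA_real_)
  }
  log((counts_mut_t / counts_wt_t) * (counts_wt_0 / counts_mut_0), base = base)
}
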