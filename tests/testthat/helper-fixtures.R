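# Shared fixture builders: all fixtures are constructed in code.

# A minimal trajectory table: one population, arbitrary frequency rows.
# `freqs` is a matrix (mutations x timepoints); depth fixed so counts are
# exact when freq * depth is integral.
make_traj <- function(freqs, depth = 1000, population_id = "p1",
                      strain = "wt", regime = "1day",
                      days = seq(100, by = 100, length.out = ncol(freqs)),
                      gens_per_day = 3.3,
                      annotation = "nonsynonymous") {
  ids <- rownames(freqs) %||% paste0("m", seq_len(nrow(freqs)))
  df <- data.frame(
    mutation_id = rep(ids, times = ncol(freqs)),
    population_id = population_id, strain = strain, regime = regime,
    gene_id = "g1", annotation_class = annotation,
    day = rep(days, each = nrow(freqs)),
    generations = rep(days * gens_per_day, each = nrow(freqs)),
    alt_count = as.vector(round(freqs * depth)),
    depth = depth,
    stringsAsFactors = FALSE
  )
  estimate_frequencies(trajectory_matrix(df))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Equal-length gene catalog.
make_catalog <- function(n, len = 900, sets = list()) {
  gene_catalog(sprintf("g%03d", seq_len(n)), rep(len, n), sets = sets)
}

# Brute-force upper Poisson tail by direct term summation.
poisson_tail_oracle <- function(n_i, lambda, kmax = 500) {
  if (n_i == 0) return(1)
  k <- 0:(n_i - 1)
  1 - sum(exp(-lambda) * lambda^k / factorial(k))
}

# Skellam pmf by direct double-Poisson convolution.
skellam_oracle <- function(k, mu1, mu2, nmax = 300) {
  n2 <- 0:nmax
  sum(stats::dpois(k + n2, mu1) * stats::dpois(n2, mu2))
}

# All nonnegative integer tables with the given margins (small cases only).
enumerate_margin_tables <- function(row_margins, col_margins) {
  stopifnot(length(col_margins) == 2)
  grids <- lapply(row_margins, function(r) 0:r)
  combos <- expand.grid(grids)
  keep <- rowSums(combos) == col_margins[1]
  combos <- combos[keep, , drop = FALSE]
  lapply(seq_len(nrow(combos)), function(i) {
    c1 <- as.numeric(combos[i, ])
    cbind(c1, row_margins - c1)
  })
}
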