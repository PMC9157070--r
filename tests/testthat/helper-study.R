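# Study-level helpers shared by the acceptance blocks: summary statistics of
# a simulated trajectory matrix (medians of the three trajectory measures,
# with the direction ratio summarized by its spread around 1).

sim_measure_medians <- function(sim) {
  f <- sim$freq
  if (!nrow(f)) return(c(fmax = NA, rate = NA, ratio_breadth = NA))
  gens <- sim$sample_gens
  fmax <- apply(f, 1, max)
  prev <- f[, -ncol(f), drop = FALSE]
  nxt <- f[, -1, drop = FALSE]
  dtau <- matrix(rep(diff(gens), each = nrow(f)), nrow = nrow(f))
  seg <- prev > 0
  rate <- abs(nxt - prev)[seg] / dtau[seg]
  ratio <- (nxt[seg] / prev[seg])
  c(fmax = stats::median(fmax),
    rate = stats::median(rate),
    ratio_breadth = stats::median(abs(log(ratio[ratio > 0]))))
}

# The reduced-scale seed-bank study grid: fixed conditions (see the methods
# vignette), one simulation per (D, replicate).
run_td_grid <- function(D_grid = c(1e2, 1e3, 1e4, 1e5), replicates = 10,
                        A = 1e4, c = 10, Ub = 3.28e-10, generations = 500,
                        seed = 20220501) {
  rows <- list()
  for (di in seq_along(D_grid)) {
    D <- D_grid[di]
    p <- seed_bank_params(A = A, D = D, c = c, Ub = Ub, Lgenome = 4.29e6,
                          dfe_scale = 1e-2, generations = generations,
                          seed = seed)
    for (r in seq_len(replicates)) {
      sim <- run_simulation(p, replicate = di * 1000 + r)
      med <- sim_measure_medians(sim)
      rows[[length(rows) + 1L]] <- data.frame(
        D = D, Td = D / c, replicate = r, t(med))
    }
  }
  do.call(rbind, rows)
}
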