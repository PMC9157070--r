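# Unit and property tests of the compartmental Wright-Fisher simulator.

test_that("compartment totals are conserved through every step", {
  p <- seed_bank_params(A = 500, D = 200, c = 20, Ub = 1e-8,
                        Lgenome = 4.29e6, generations = 1, seed = 7)
  set.seed(7)
  state <- new_lineage_state(p)
  for (t in 1:30) {
    state$gen <- t
    state <- step_metabolic_exchange(state, p)
    expect_equal(sum(state$active), p$A)
    expect_equal(sum(state$dormant), p$D)
    state <- step_mutation(state, p)
    expect_equal(sum(state$active), p$A)
    state <- step_selection_reproduction(state, p)
    expect_equal(sum(state$active), p$A)
    expect_equal(sum(state$dormant), p$D)
    expect_true(all(state$active >= 0 & state$dormant >= 0))
  }
})

test_that("no exchange happens when c = 0", {
  p <- suppressWarnings(seed_bank_params(A = 100, D = 50, c = 0))
  state <- new_lineage_state(p)
  expect_identical(step_metabolic_exchange(state, p), state)
})

test_that("c = D means every dormant individual resuscitates each generation", {
  p <- seed_bank_params(A = 100, D = 50, c = 50, Ub = 0, generations = 20,
                        seed = 1)
  sim <- run_simulation(p)
  expect_true(length(sim$dwell_times) > 0)
  expect_true(all(sim$dwell_times == 1))
})

test_that("dwell times are geometric with mean D/c and matching variance", {
  p <- seed_bank_params(A = 500, D = 500, c = 25, Ub = 0, generations = 800,
                        seed = 11)
  sim <- run_simulation(p, record_interval = 400)
  td <- p$D / p$c # 20 generations
  n <- length(sim$dwell_times)
  expect_gt(n, 3000)
  se <- stats::sd(sim$dwell_times) / sqrt(n)
  expect_lt(abs(mean(sim$dwell_times) - td), 3 * se)
  pr <- p$c / p$D
  expect_lt(abs(stats::var(sim$dwell_times) - (1 - pr) / pr^2),
            0.15 * (1 - pr) / pr^2)
})

test_that("mutation input matches the Poisson supply A*Ub*Lgenome", {
  p <- seed_bank_params(A = 1e4, D = 0, c = 0, Ub = 3.28e-9,
                        Lgenome = 4.29e6, generations = 100, seed = 3)
  supply <- p$A * p$Ub * p$Lgenome
  expect_equal(supply, 140.712, tolerance = 1e-6)
  sim <- run_simulation(p, record_interval = 1e9)
  se <- sqrt(supply / length(sim$supply))
  expect_lt(abs(mean(sim$supply) - supply), 3 * se)
  # fitness effects are Exponential(dfe_scale)
  s <- sim$mut_effects[sim$mut_effects > 0]
  expect_lt(abs(mean(s) - p$dfe_scale),
            3 * p$dfe_scale / sqrt(length(s)))
})

test_that("Ub = 0 yields no mutations ever", {
  p <- seed_bank_params(A = 200, D = 50, c = 5, Ub = 0, generations = 50,
                        seed = 5)
  sim <- run_simulation(p)
  expect_equal(nrow(sim$freq), 0)
  expect_true(all(sim$supply == 0))
})

test_that("selection weights follow exp(s): a log-2 advantage doubles output", {
  p <- seed_bank_params(A = 2e4, D = 0, c = 0, Ub = 0, generations = 1)
  set.seed(42)
  state <- new_lineage_state(p, init = list(active = c(1e4, 1e4),
                                            fitness = c(0, log(2))))
  draws <- replicate(200, {
    s2 <- step_selection_reproduction(state, p)
    s2$active[2] / p$A
  })
  # expected share of the fitter lineage: 2/3
  se <- sqrt((2 / 3) * (1 / 3) / p$A) / sqrt(200)
  expect_lt(abs(mean(draws) - 2 / 3), 4 * se)
})

test_that("equal fitness reduces reproduction to symmetric multinomial drift", {
  p <- seed_bank_params(A = 1000, D = 0, c = 0, Ub = 0, generations = 1)
  set.seed(9)
  state <- new_lineage_state(p, init = list(active = c(500, 500)))
  draws <- replicate(300, step_selection_reproduction(state, p)$active[1])
  expect_lt(abs(mean(draws) - 500), 4 * sqrt(1000 * 0.25 / 300))
})

test_that("neutral fixation probability equals the initial frequency", {
  # brute-force Monte-Carlo over full runs; the analytic oracle is p itself
  fixed <- vapply(1:1500, function(r) {
    p <- seed_bank_params(A = 100, D = 0, c = 0, Ub = 0, generations = 5000,
                          seed = 2000)
    sim <- run_simulation(p, init = list(active = c(90, 10),
                                         muts = list(integer(0), 1L)),
                          record_interval = 1e9, stop_on_absorption = TRUE,
                          replicate = r)
    sim$freq["1", ncol(sim$freq)] == 1
  }, logical(1))
  se <- sqrt(0.1 * 0.9 / length(fixed))
  expect_lt(abs(mean(fixed) - 0.1), 3.5 * se)
})

test_that("without a seed bank the dynamics match a plain Wright-Fisher chain", {
  # oracle: direct binomial sampling chain, independent of the simulator
  A <- 200; T <- 40; nrep <- 300
  set.seed(123)
  oracle_fmax <- replicate(nrep, {
    f <- 0.1
    path <- numeric(T)
    for (t in 1:T) {
      f <- stats::rbinom(1, A, f) / A
      path[t] <- f
    }
    max(path)
  })
  sim_fmax <- vapply(1:nrep, function(r) {
    p <- seed_bank_params(A = A, D = 0, c = 0, Ub = 0, generations = T,
                          seed = 7000)
    sim <- run_simulation(p, init = list(active = c(180, 20),
                                         muts = list(integer(0), 1L)),
                          record_interval = 1, replicate = r)
    max(sim$freq["1", -1])
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(oracle_fmax, sim_fmax))$p.value,
            0.01)
})

test_that("identical seeds give bit-identical results", {
  p <- seed_bank_params(A = 300, D = 100, c = 10, Ub = 1e-8,
                        Lgenome = 4.29e6, generations = 60, seed = 99)
  expect_identical(run_simulation(p), run_simulation(p))
})

test_that("frequencies stay in [0, 1] and a lone founder stays fixed", {
  p <- seed_bank_params(A = 300, D = 100, c = 10, Ub = 1e-7,
                        Lgenome = 4.29e6, generations = 80, seed = 13)
  sim <- run_simulation(p)
  expect_true(all(sim$freq >= 0 & sim$freq <= 1))
  p0 <- seed_bank_params(A = 50, D = 0, c = 0, Ub = 0, generations = 10,
                         seed = 1)
  sim0 <- run_simulation(p0, init = list(active = 50, muts = list(1L)),
                         record_interval = 1)
  expect_true(all(sim0$freq["1", ] == 1))
})

test_that("replicates are seeded independently and reproducibly", {
  p <- seed_bank_params(A = 200, D = 50, c = 5, Ub = 1e-8, Lgenome = 4.29e6,
                        generations = 30, replicates = 3, seed = 5)
  reps <- run_replicates(p)
  expect_length(reps, 3)
  expect_identical(reps[[2]], run_simulation(p, replicate = 2))
  expect_false(identical(reps[[1]]$freq, reps[[2]]$freq) &&
                 identical(reps[[1]]$supply, reps[[2]]$supply))
})
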