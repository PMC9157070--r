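# Forward-time Wright-Fisher simulation with an active/dormant compartment
# structure.  Lineage-count (genotype-class) bookkeeping is used rather than
# per-individual records, so large A stays tractable; the two representations
# are distributionally identical.
#
# Each generation applies three steps in order:
#   (1) change of metabolic state: active individuals enter the seed bank with
#       probability c/A, dormant individuals resuscitate with probability c/D,
#       with a repair step restoring exact compartment totals;
#   (2) mutation: Poisson(A * Ub * Lgenome) new beneficial mutations land on
#       uniformly chosen active individuals, each with an Exponential(dfe_scale)
#       fitness effect; dormant individuals acquire no mutations;
#   (3) selection/reproduction: A offspring are drawn multinomially with
#       per-individual weight exp(s_i), s_i = X_i - Xbar over active
#       individuals; the dormant compartment is carried unchanged.

#' Create the initial lineage state for a simulation
#'
#' A lineage is a class of individuals sharing the same set of mutations and
#' hence the same log fitness.  The state tracks per-lineage active and
#' dormant counts, fitness, and mutation sets, plus dormancy age cohorts used
#' to sample dwell times.
#'
#' @param params A [seed_bank_params()] object.
#' @param init Optional list with elements `active` (counts per lineage,
#'   summing to `A`), `dormant` (counts summing to `D`; defaults to all mass
#'   on the first lineage), `fitness` (log fitness per lineage) and `muts`
#'   (list of integer mutation-id vectors per lineage), used to start runs
#'   from a polymorphic state with tracked lineages.
#' @return A `lineage_state` object.
#' @export
new_lineage_state <- function(params, init = NULL) {
  stopifnot(inherits(params, "seedbank_params"))
  if (is.null(init)) {
    active <- params$A
    dormant <- params$D
    fitness <- 0
    muts <- list(integer(0))
  } else {
    active <- as.numeric(init$active)
    k <- length(active)
    dormant <- as.numeric(init$dormant %||% c(params$D, rep(0, k - 1)))
    fitness <- as.numeric(init$fitness %||% rep(0, k))
    muts <- init$muts %||% rep(list(integer(0)), k)
    if (length(dormant) != k || length(fitness) != k || length(muts) != k) {
      stopf("init components must all have the same length")
    }
    if (sum(active) != params$A) stopf("init active counts must sum to A")
    if (sum(dormant) != params$D) stopf("init dormant counts must sum to D")
  }
  init_ids <- unique(unlist(muts))
  mut_s <- stats::setNames(rep(0, length(init_ids)), as.character(init_ids))
  structure(
    list(
      active = active, dormant = dormant, fitness = fitness, muts = muts,
      gen = 0L,
      # dormancy cohorts: entry generation (-1 = present at start, censored)
      dorm_entry_gen = if (params$D > 0) -1L else integer(0),
      dorm_entry_count = if (params$D > 0) params$D else numeric(0),
      dwell_samples = numeric(0),
      mut_s = mut_s,
      next_mut_id = if (length(init_ids)) max(init_ids) + 1L else 1L,
      last_supply = 0
    ),
    class = "lineage_state"
  )
}

# Multivariate hypergeometric draw: choose `k` individuals uniformly
# without replacement from bins with the given counts; returns per-bin
# draw counts.
draw_mvh <- function(counts, k) {
  total <- sum(counts)
  idx <- sample.int(total, k)
  bounds <- cumsum(c(0, counts))
  tabulate(findInterval(idx - 0.5, bounds), nbins = length(counts))
}

#' Metabolic exchange step (active <-> dormant)
#'
#' Exactly `c` uniformly chosen active individuals enter dormancy and
#' exactly `c` uniformly chosen dormant individuals resuscitate, so each
#' active individual moves with probability `c/A`, each dormant individual
#' with probability `c/D`, and the compartment totals stay at exactly `A`
#' and `D` by construction.  Dwell-time bookkeeping is updated from the
#' dormancy age cohorts: the resuscitated individuals are an exchangeable
#' uniform draw from the dormant pool, so their entry ages follow a
#' multivariate hypergeometric over the age cohorts.
#'
#' @param state A `lineage_state`.
#' @param params A [seed_bank_params()] object.
#' @return The updated `lineage_state`.
#' @export
step_metabolic_exchange <- function(state, params) {
  if (params$c == 0) return(state)
  if (params$D == 0) stopf("c > 0 with D = 0 is not a valid configuration")
  moved <- params$c
  n_in <- draw_mvh(state$active, moved)
  n_out <- draw_mvh(state$dormant, moved)

  # dwell bookkeeping over age cohorts
  cohort_draw <- draw_mvh(state$dorm_entry_count, moved)
  drawn <- which(cohort_draw > 0)
  entries <- rep(state$dorm_entry_gen[drawn], cohort_draw[drawn])
  # only entrants from the first half of the run contribute dwell samples:
  # late entrants are right-truncated by the end of the run, which would
  # bias the mean downward (initial dormants, entry -1, are censored too)
  tracked <- entries >= 0 & entries <= params$generations / 2
  if (any(tracked)) {
    state$dwell_samples <- c(state$dwell_samples, state$gen - entries[tracked])
  }
  state$dorm_entry_count <- state$dorm_entry_count - cohort_draw
  keep <- state$dorm_entry_count > 0
  state$dorm_entry_gen <- state$dorm_entry_gen[keep]
  state$dorm_entry_count <- state$dorm_entry_count[keep]
  # new entrants form a cohort stamped with the current generation
  state$dorm_entry_gen <- c(state$dorm_entry_gen, state$gen)
  state$dorm_entry_count <- c(state$dorm_entry_count, moved)

  state$active <- state$active - n_in + n_out
  state$dormant <- state$dormant + n_in - n_out
  state
}

#' Mutation step
#'
#' Draws a Poisson(`A * Ub * Lgenome`) number of new beneficial mutations and
#' assigns each to a uniformly chosen active individual, which founds a new
#' lineage carrying its parent's mutations plus the new one.  Fitness effects
#' are Exponential(`dfe_scale`); dormant individuals acquire no mutations.
#'
#' @inheritParams step_metabolic_exchange
#' @return The updated `lineage_state`.
#' @export
step_mutation <- function(state, params) {
  supply <- params$A * params$Ub * params$Lgenome
  state$last_supply <- 0
  if (supply == 0) return(state)
  n_mut <- stats::rpois(1, supply)
  state$last_supply <- n_mut
  if (n_mut == 0) return(state)
  if (sum(state$active) < 1) stopf("active compartment is empty")
  s_new <- stats::rexp(n_mut, rate = 1 / params$dfe_scale)
  for (j in seq_len(n_mut)) {
    parent <- sample.int(length(state$active), 1L, prob = state$active)
    id <- state$next_mut_id
    state$next_mut_id <- id + 1L
    state$active[parent] <- state$active[parent] - 1
    state$active <- c(state$active, 1)
    state$dormant <- c(state$dormant, 0)
    state$fitness <- c(state$fitness, state$fitness[parent] + s_new[j])
    state$muts <- c(state$muts, list(c(state$muts[[parent]], id)))
    state$mut_s[as.character(id)] <- s_new[j]
  }
  state
}

#' Selection and reproduction step
#'
#' Computes selection coefficients `s_i = X_i - Xbar` over active individuals
#' (after the mutation step) and draws `A` offspring multinomially with
#' per-individual weight `exp(s_i)`; dormant individuals do not reproduce and
#' are carried unchanged.  Lineages left with no members are pruned.
#'
#' @inheritParams step_metabolic_exchange
#' @return The updated `lineage_state`.
#' @export
step_selection_reproduction <- function(state, params) {
  act <- state$active
  pos <- act > 0
  xbar <- sum(act[pos] * state$fitness[pos]) / params$A
  w <- numeric(length(act))
  # lineage weight = (class size) * exp(s_i); subtracting xbar only
  # normalises, but keeps exp() well-scaled
  w[pos] <- act[pos] * exp(state$fitness[pos] - xbar)
  state$active <- as.numeric(stats::rmultinom(1, params$A, w))
  keep <- state$active > 0 | state$dormant > 0
  if (!all(keep)) {
    state$active <- state$active[keep]
    state$dormant <- state$dormant[keep]
    state$fitness <- state$fitness[keep]
    state$muts <- state$muts[keep]
  }
  state
}

# Per-mutation carrier frequencies of the current state under the given
# compartment scope; returns a named numeric vector (possibly empty).
state_frequencies <- function(state, params, scope = "combined") {
  ids <- unlist(state$muts)
  if (!length(ids)) return(stats::setNames(numeric(0), character(0)))
  len <- lengths(state$muts)
  if (scope == "combined") {
    w <- rep(state$active + state$dormant, len)
    denom <- params$A + params$D
  } else {
    w <- rep(state$active, len)
    denom <- params$A
  }
  counts <- rowsum(w, ids)
  stats::setNames(as.numeric(counts) / denom, rownames(counts))
}

#' Run a seed-bank Wright-Fisher simulation
#'
#' Applies the metabolic-exchange, mutation, and selection/reproduction steps
#' in that order for `params$generations` generations, recording per-mutation
#' frequency trajectories at a fixed sampling interval.  Frequencies are
#' reported over the combined active + dormant pool by default, mirroring
#' pooled sequencing of vegetative cells and spores together; `scope =
#' "active"` restricts to the active compartment.
#'
#' @param params A [seed_bank_params()] object.
#' @param init Optional initial state specification; see [new_lineage_state()].
#' @param record_interval Generations between recorded samples (default 10,
#'   mirroring sparse empirical sampling).  Generation 0 and the final
#'   generation are always recorded.
#' @param scope `"combined"` (default) or `"active"` frequency scope.
#' @param stop_on_absorption If `TRUE` (and `Ub = 0`), stop early once every
#'   tracked mutation is lost or fixed.
#' @param replicate Optional replicate index `r`; the run is then seeded with
#'   `params$seed + r`.
#' @return A `seedbank_sim` object with elements `freq` (mutations x
#'   timepoints frequency matrix), `sample_gens`, `mean_fitness`,
#'   `dwell_times`, `supply` (realized mutation input per generation),
#'   `mut_effects`, `final_state`, `params`, `scope` and `seed_used`.
#'   Dwell-time samples come from individuals entering dormancy in the
#'   first half of the run; their mean estimates `D/c` without bias only
#'   when the run is long relative to `D/c` (a horizon of at least ~40
#'   dwell times is comfortable) — shorter runs still right-truncate the
#'   longest dwells.
#' @examples
#' p <- seed_bank_params(A = 200, D = 50, c = 5, Ub = 1e-8, Lgenome = 4.29e6,
#'                       generations = 50, seed = 42)
#' sim <- run_simulation(p)
#' sim$sample_gens
#' @export
run_simulation <- function(params, init = NULL, record_interval = 10L,
                           scope = c("combined", "active"),
                           stop_on_absorption = FALSE, replicate = NULL) {
  stopifnot(inherits(params, "seedbank_params"))
  scope <- match.arg(scope)
  seed_used <- if (!is.null(params$seed)) {
    as.integer(params$seed + (replicate %||% 0L))
  } else NULL
  with_seed(seed_used, {
    state <- new_lineage_state(params, init)
    denom_all <- params$A + params$D
    samples <- list(`0` = state_frequencies(state, params, scope))
    mean_fitness <- c(sum(state$active * state$fitness) / params$A)
    supply <- numeric(0)
    gens_run <- 0L
    for (t in seq_len(params$generations)) {
      state$gen <- t
      state <- step_metabolic_exchange(state, params)
      state <- step_mutation(state, params)
      state <- step_selection_reproduction(state, params)
      supply <- c(supply, state$last_supply)
      gens_run <- t
      record <- (t %% record_interval == 0L) || t == params$generations
      absorbed <- FALSE
      if (stop_on_absorption && params$Ub == 0) {
        absorbed <- length(state$active) == 1L || {
          fr <- state_frequencies(state, params, scope)
          all(fr %in% c(0, 1))
        }
        record <- record || absorbed
      }
      if (record) {
        samples[[as.character(t)]] <- state_frequencies(state, params, scope)
        mean_fitness <- c(mean_fitness,
                          sum(state$active * state$fitness) / params$A)
      }
      if (absorbed) break
    }
    all_ids <- unique(unlist(lapply(samples, names)))
    freq <- matrix(0, nrow = length(all_ids), ncol = length(samples),
                   dimnames = list(all_ids, names(samples)))
    for (j in seq_along(samples)) {
      s <- samples[[j]]
      if (length(s)) freq[names(s), j] <- s
    }
    structure(
      list(freq = freq,
           sample_gens = as.integer(names(samples)),
           mean_fitness = mean_fitness,
           dwell_times = state$dwell_samples,
           supply = supply,
           mut_effects = state$mut_s,
           final_state = state,
           generations_run = gens_run,
           params = params, scope = scope, seed_used = seed_used),
      class = "seedbank_sim"
    )
  })
}

#' Run replicate simulations
#'
#' Runs `params$replicates` independent simulations; replicate `r` is seeded
#' with `params$seed + r` so the set is reproducible yet independent.
#'
#' @inheritParams run_simulation
#' @param ... Passed to [run_simulation()].
#' @return A list of `seedbank_sim` objects.
#' @export
run_replicates <- function(params, ...) {
  lapply(seq_len(params$replicates), function(r) {
    run_simulation(params, replicate = r, ...)
  })
}

#' @export
print.seedbank_sim <- function(x, ...) {
  cat("Seed-bank Wright-Fisher simulation\n")
  cat(sprintf("  A = %g, D = %g, c = %g; %d generations run, scope = %s\n",
              x$params$A, x$params$D, x$params$c, x$generations_run, x$scope))
  cat(sprintf("  %d mutations recorded at %d sample points\n",
              nrow(x$freq), ncol(x$freq)))
  cat(sprintf("  final mean active fitness: %.5f\n",
              x$mean_fitness[length(x$mean_fitness)]))
  if (length(x$dwell_times)) {
    cat(sprintf("  %d dwell-time samples, mean %.2f generations\n",
                length(x$dwell_times), mean(x$dwell_times)))
  }
  invisible(x)
}

#' @export
plot.seedbank_sim <- function(x, max_mutations = 100, ...) {
  f <- x$freq
  if (!nrow(f)) {
    graphics::plot(x$sample_gens, x$mean_fitness, type = "l",
                   xlab = "generation", ylab = "mean fitness", ...)
    return(invisible(x))
  }
  if (nrow(f) > max_mutations) {
    keep <- order(apply(f, 1, max), decreasing = TRUE)[seq_len(max_mutations)]
    f <- f[keep, , drop = FALSE]
  }
  graphics::matplot(x$sample_gens, t(f), type = "l", lty = 1,
                    col = grDevices::adjustcolor("steelblue", 0.5),
                    xlab = "generation", ylab = "mutation frequency",
                    ylim = c(0, 1), ...)
  invisible(x)
}
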