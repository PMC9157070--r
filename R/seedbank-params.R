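#' Parameters for the seed-bank Wright-Fisher simulator
#'
#' Configuration of a forward-time Wright-Fisher simulation of an adapting
#' population structured into `A` active individuals and a seed bank of `D`
#' dormant individuals.  Each generation, `c` individuals exchange metabolic
#' state in each direction: an active individual enters dormancy with
#' probability `c/A` and a dormant individual resuscitates with probability
#' `c/D`, so compartment sizes stay constant.  Beneficial mutations arrive in
#' the active compartment as a Poisson process with mean `A * Ub * Lgenome`
#' per generation, with effects drawn from an exponential distribution of
#' fitness effects.
#'
#' The mean number of generations an individual spends dormant is
#' `D/c` and the active:dormant ratio is `K = A/D`.
#'
#' @param A Number of active individuals (constant over the run).
#' @param D Number of dormant individuals (constant; 0 disables the seed bank).
#' @param c Number of individuals exchanging metabolic state per generation,
#'   in each direction.  May also be given as a fraction of `A` via
#'   `c_units = "fraction"`.
#' @param Ub Beneficial mutation rate per individual per base pair per
#'   generation.
#' @param Lgenome Genome length in base pairs.
#' @param dfe_scale Scale (= mean) of the exponential distribution of
#'   beneficial fitness effects.
#' @param generations Number of generations to simulate.
#' @param replicates Number of independent replicate runs.
#' @param seed Integer RNG seed; replicate `r` uses `seed + r`.
#' @param c_units Either `"count"` (default; `c` is a number of individuals)
#'   or `"fraction"` (`c` is a fraction of `A`, converted to a count).
#'
#' @return An object of class `seedbank_params`.
#' @examples
#' p <- seed_bank_params(A = 1000, D = 100, c = 10, Ub = 1e-9,
#'                       Lgenome = 4.29e6, generations = 100, seed = 1)
#' mean_dormancy_time(p) # D/c = 10 generations
#' @export
seed_bank_params <- function(A, D = 0, c = 0, Ub = 0, Lgenome = 4.29e6,
                             dfe_scale = 1e-2, generations = 100L,
                             replicates = 1L, seed = NULL,
                             c_units = c("count", "fraction")) {
  c_units <- match.arg(c_units)
  if (!is_number(A) || A < 1) stopf("A must be a number >= 1, got %s", A)
  if (!is_number(D) || D < 0) stopf("D must be a number >= 0, got %s", D)
  if (c_units == "fraction") c <- c * A
  if (!is_number(c) || c < 0) stopf("c must be a number >= 0, got %s", c)
  if (c != round(c)) {
    warnf("c rounded to a whole count of individuals (%g -> %g)", c, round(c))
    c <- round(c)
  }
  if (D == 0 && c > 0) stopf("c > 0 requires a dormant compartment (D > 0)")
  if (D > 0 && c > min(A, D)) {
    stopf("c (%g) must not exceed min(A, D) = %g", c, min(A, D))
  }
  if (!is_number(Ub) || Ub < 0) stopf("Ub must be >= 0")
  if (!is_number(Lgenome) || Lgenome <= 0) stopf("Lgenome must be > 0")
  if (!is_number(dfe_scale) || dfe_scale <= 0) stopf("dfe_scale must be > 0")
  if (!is_number(generations) || generations < 0) stopf("generations must be >= 0")
  if (D > 0 && c == 0) {
    warnf("D > 0 with c = 0: the seed bank is permanently inert")
  }
  structure(
    list(A = as.numeric(A), D = as.numeric(D), c = as.numeric(c),
         Ub = Ub, Lgenome = Lgenome, dfe_scale = dfe_scale,
         generations = as.integer(generations),
         replicates = as.integer(replicates),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "seedbank_params"
  )
}

#' @export
print.seedbank_params <- function(x, ...) {
  cat("Seed-bank Wright-Fisher parameters\n")
  cat(sprintf("  A = %g active, D = %g dormant, c = %g exchanged/generation\n",
              x$A, x$D, x$c))
  if (x$D > 0 && x$c > 0) {
    cat(sprintf("  <Td> = D/c = %g generations, K = A/D = %g\n",
                x$D / x$c, x$A / x$D))
  }
  cat(sprintf("  Ub = %g /ind/bp/gen, Lgenome = %g bp (supply %.4g /gen)\n",
              x$Ub, x$Lgenome, x$A * x$Ub * x$Lgenome))
  cat(sprintf("  DFE: Exponential(scale = %g); %d generations, %d replicate(s)\n",
              x$dfe_scale, x$generations, x$replicates))
  invisible(x)
}

#' Mean dormancy (seed-bank residence) time
#'
#' Returns the mean number of generations an individual spends in the dormant
#' state, `D/c`.  Dwell times are geometric with success probability `c/D`,
#' so the mean residence time is `D/c`.
#'
#' @param params A [seed_bank_params()] object.
#' @return Mean dwell time in generations; `Inf` (with a warning) when `c = 0`
#'   and `D > 0`, `NaN` when there is no seed bank at all.
#' @seealso [active_dormant_ratio()]
#' @export
mean_dormancy_time <- function(params) {
  stopifnot(inherits(params, "seedbank_params"))
  if (params$D == 0) return(NaN)
  if (params$c == 0) {
    warnf("c = 0: dwell time is infinite (inert seed bank)")
    return(Inf)
  }
  params$D / params$c
}

#' Active to dormant ratio K = A/D
#'
#' @param params A [seed_bank_params()] object.
#' @return `A/D`; `Inf` when `D = 0`.
#' @export
active_dormant_ratio <- function(params) {
  stopifnot(inherits(params, "seedbank_params"))
  if (params$D == 0) return(Inf)
  params$A / params$D
}

#' Parameters for the two-locus seed-bank simulation
#'
#' Two biallelic loci segregate in a population with active and dormant
#' compartments.  Each generation active individuals exchange state with the
#' seed bank as in [seed_bank_params()], then reproduce with recombination:
#' with probability `r_rec` an offspring takes its second-locus allele from an
#' independently chosen parent.
#'
#' @param A,D,c,generations,seed As in [seed_bank_params()].
#' @param init_freq Length-2 vector of initial frequencies of the two focal
#'   alleles (both placed on the same founder haplotype).
#' @param r_rec Per-individual per-generation recombination probability in
#'   `[0, 1]`.
#' @param s Length-2 vector of selection coefficients of the two alleles.
#' @return An object of class `two_locus_params`.
#' @export
two_locus_params <- function(A, D = 0, c = 0, init_freq = c(0.1, 0.1),
                             r_rec = 0, s = c(0, 0), generations = 100L,
                             seed = NULL) {
  base <- seed_bank_params(A = A, D = D, c = c, Ub = 0,
                           generations = generations, seed = seed)
  if (length(init_freq) != 2 || any(init_freq < 0) || any(init_freq > 1)) {
    stopf("init_freq must be two frequencies in [0, 1]")
  }
  if (!is_number(r_rec) || r_rec < 0 || r_rec > 1) {
    stopf("r_rec must be a probability in [0, 1]")
  }
  if (length(s) != 2 || !all(is.finite(s))) stopf("s must be two finite numbers")
  structure(
    c(base[c("A", "D", "c", "generations", "seed")],
      list(init_freq = as.numeric(init_freq), r_rec = r_rec, s = as.numeric(s))),
    class = "two_locus_params"
  )
}
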