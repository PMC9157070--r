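# seedbankevo

Seed-bank Wright–Fisher simulation and molecular-evolution statistics.

Many microbes weather resource scarcity by entering a reversible dormant
state; the resulting pool of dormant, non-reproducing individuals — a *seed
bank* — is expected to buffer both genetic drift and selection, slowing
molecular evolution while raising the diversity a population can hold.
`seedbankevo` is for population geneticists and experimental-evolution
groups who want to (a) simulate adapting populations with an active/dormant
compartment structure and (b) analyse pooled-sequencing mutation
trajectories from serially transferred populations with the statistics that
quantify those seed-bank effects.

## The models

**Compartmental Wright–Fisher simulator.** A population of `A` active and
`D` dormant individuals evolves in discrete generations with three steps:
(1) metabolic exchange — exactly `c` uniformly chosen individuals move in
each direction, so each active individual enters the seed bank with
probability `c/A` and each dormant individual resuscitates with probability
`c/D`; dwell times are geometric with mean `⟨Td⟩ = D/c`; (2) beneficial
mutation in the active compartment only, Poisson(`A·Ub·Lgenome`) per
generation with exponential fitness effects; (3) multinomial
selection/reproduction of the `A` active individuals with weights
`exp(X_i − X̄)`. A two-locus variant adds recombination at per-individual
probability `r_rec`.

**Trajectory statistics.** Naive frequency estimation `f̂ = F/G` from pooled
counts; the diversity accumulation `M(t) = Σ_m f̂` and its hyperbolic model

    log10 M(t*) = log10 M(0) + [log10 M]max · t*/(t*₁/₂ + t*)

fit by 54-start BFGS least squares; per-trajectory measures `f_max`,
`|Δf|/Δτ`, and the direction ratio `f(τ+Δτ)/f(τ)` with survival-curve and
Kolmogorov–Smirnov comparisons (Benjamini–Hochberg corrected); threshold
fate calling, extinction probabilities, pairwise trajectory correlations (a
recombination proxy), site-weighted pN/pS, generation arithmetic
`Δτ = log2(Nf/Ni)`, and relative log fitness.

**Gene-level parallelism.** Multiplicity `m_i = n_i·L̄/L_i`, the
genome-wide parallelism score `Δℓ = Σ n_i log(m_i/m̄)` with permutation and
subsampling controls, per-gene Poisson enrichment P-values with a
survival-curve false-discovery threshold `P*` (count filter `n_i ≥ 3`),
binomial region/regulon enrichment, and codon-level effective
nonsynonymous gene lengths.

**Convergence/divergence.** Exact hypergeometric nulls for
significant-gene-set overlap; the mean absolute difference of relative
multiplicities `⟨ΔM⟩` standardized (`Z⟨ΔM⟩`) against a fixed-margin
contingency-table permutation null (Patefield's algorithm; positive `Z` =
divergence); Skellam tests for genes preferentially enriched in one cohort.

**Synthetic data.** A generator emulating pooled sequencing of serially
transferred populations — simulator or logistic-surrogate truth, negative
binomial depth, binomial read noise, a 0.01 detection floor, planted
enriched gene sets, and synthetic genomes (FASTA + GFF3) — so the whole
pipeline is testable end to end without external data.

## Worked example

Simulate a population with a seed bank (`⟨Td⟩ = 100` generations), sequence
it at 100x, and summarize diversity accumulation:

```r
library(seedbankevo)

p <- seed_bank_params(A = 1e4, D = 1e3, c = 10, Ub = 3.28e-10,
                      Lgenome = 4.29e6, dfe_scale = 1e-2,
                      generations = 500, seed = 42)
sim <- run_simulation(p)
sim
#> Seed-bank Wright-Fisher simulation
#>   A = 10000, D = 1000, c = 10; 500 generations run, scope = combined
#>   2182 mutations recorded at 51 sample points
#>   final mean active fitness: 0.24953
#>   2428 dwell-time samples, mean 90.25 generations

traj <- sim_to_trajectories(sim, population_id = "p1", depth = 100)
mt <- sum_derived_frequencies(traj)
fit <- fit_diversity_model(mt$day, mt$M, per_day_generations = 1)
fit
#> Hyperbolic diversity-accumulation fit
#>   log10 M(0)      = -2.0152
#>   [log10 M]max    = 3.3478
#>   t*_1/2 (days)   = 89.0765
#>   tau_1/2 (gens)  = 89.0765  (x 1 generations/day)
#>   SSR = 0.272 over 50 points; 53/54 starts converged
```

The population accumulated `M(500) ≈ 6` summed derived allele frequency;
the fitted half-time of ~89 generations says diversity accumulates on the
same timescale as the mean dormancy time, and the mean active fitness rose
by ~0.25 over the run.

Detect planted targets of selection in a synthetic gene-count table:

```r
spec <- synthetic_spec(strains = "wt", n_genes = 1000, n_planted = 10,
                       planted_multiplier = 10, seed = 3)
genome <- generate_genome(spec)
gc <- generate_gene_counts(spec, genome$catalog)
counts <- setNames(gc$counts[, 1], rownames(gc$counts))
enr <- gene_enrichment(counts[counts > 0], genome$catalog)
enr
#> Gene-level parallelism
#>   1000 genes, 1976 mutations; delta_ell = 903.913 (mbar = 1.976)
#>   P* = 3.81e-06 (alpha = 0.05, count filter >= 3, survival-curve rule): 10 significant gene(s)
#>    gene0071, gene0307, gene0371, gene0504, gene0587, gene0684, gene0698, gene0757, gene0771, gene0819

length(intersect(significant_genes(enr), gc$planted[[1]]))
#> [1] 10   # all ten planted genes recovered
```

`Δℓ ≈ 904` is the genome-wide excess log likelihood of gene-specific
multiplicities over the size-proportional null; `P*` is the survival-curve
false-discovery threshold at `α = 0.05`.

Serial-transfer generation arithmetic:

```r
estimate_generations(10, 1, n_transfers = 700)
#> Generations per transfer: 3.322; total over 700 transfers: 2325.3
```

A command-line pipeline (`simulate`, `synth`, `trajstats`, `fitmodel`,
`parallelism`, `convergence`, `report`) is installed as `exec/seedbankevo`;
run `seedbankevo --help` for usage.

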