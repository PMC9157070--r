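---
title: "Models and methods: seed-bank Wright-Fisher dynamics and molecular-evolution statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: seed-bank Wright-Fisher dynamics and molecular-evolution statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedbankevo)
```

seedbankevo studies how seed banks — pools of dormant, non-reproducing
individuals, such as *Bacillus* endospores — alter the molecular
evolutionary dynamics of microbial populations. It combines a forward-time
simulator of adapting populations with an active/dormant compartment
structure, the statistics used to analyse pooled-sequencing mutation
trajectories from evolve-and-resequence experiments, and gene-level
parallelism and convergence/divergence statistics. A synthetic-data
generator emulates the pooled-sequencing observation process so the entire
pipeline is testable without external data.

## The compartmental Wright-Fisher model

A population holds `A` active and `D` dormant individuals, both constant
over time. Each generation applies three steps in order:

1. **Change of metabolic state.** Exactly `c` uniformly chosen active
   individuals enter the seed bank and exactly `c` uniformly chosen dormant
   individuals resuscitate. Each active individual therefore moves with
   probability `c/A` and each dormant individual with probability `c/D`,
   and compartment totals are preserved by construction. The time an
   individual spends dormant is geometric with success probability `c/D`,
   so the mean dwell time is `<Td> = D/c`; the other natural summary is the
   active:dormant ratio `K = A/D`.
2. **Mutation.** A Poisson(`A * Ub * Lgenome`) number of new beneficial
   mutations lands on uniformly chosen active individuals. Each mutation's
   selection coefficient is drawn from an exponential distribution of
   fitness effects with scale `dfe_scale`, and the carrier's log fitness is
   incremented: `X -> X + s`. Dormant individuals do not replicate their
   genomes and acquire no mutations. Mutations follow the infinite-sites
   convention: every event is a new allele, and there is no back-mutation.
3. **Selection and reproduction.** Selection coefficients are measured
   against the current active mean, `s_i = X_i - Xbar`, and `A` offspring
   are drawn multinomially with per-individual weight `exp(s_i)`. The
   dormant compartment is carried unchanged — the seed bank neither
   reproduces nor is purged, which is precisely how it buffers both drift
   and selection.

**Why exact-`c` exchange rather than binomial draws with repair.** An
alternative bookkeeping draws per-lineage binomial numbers of movers in
each direction and then cancels the surplus on the larger side to restore
the totals. That repair truncates the exchange to the *minimum* of two
binomial draws, whose expectation is noticeably below `c` (about 18% at
`c = 10`), which inflates realized dwell times well above `D/c`. Moving
exactly `c` uniformly chosen individuals per direction keeps the
per-individual probabilities at exactly `c/A` and `c/D`, keeps compartments
constant without any repair, and makes the marginal dwell distribution
exactly geometric. Dwell-time samples are recorded only for individuals
that entered dormancy during the first half of a run; later entrants are
right-truncated by the end of the run and would bias the sample mean
downward (about 2.5% at a horizon of forty dwell times).

**Representation.** The simulator tracks lineages (genotype classes: sets
of individuals sharing a mutation set) rather than individuals, so `A` of
10^6 is tractable; the two representations are distributionally identical.
Extinct lineages are pruned each generation.

**Frequency scope.** Pooled sequencing of a transferred culture captures
vegetative cells and spores together, so reported mutation frequencies are
computed over the combined `A + D` pool by default; `scope = "active"` is
available. The choice matters: a large, slowly-mixing seed bank dilutes
combined frequencies, which is part of the buffering phenomenon itself.

**Defaults and scale.** Reference parameter values for the full-scale
system are `A = 10^6`, `c = 10` (equivalently a fraction `10^-5` of `A`),
`Ub = 3.28e-11` per individual per base pair per generation,
`Lgenome = 4.29e6` bp, and an exponential DFE with scale `10^-2`, run for
3,300 generations with `D` spanning `10^1` to `10^6`. The package's
validation studies run a reduced-scale version chosen once and used
throughout: `A = 10^4`, `c = 10`, `D` in `{10^2, 10^3, 10^4, 10^5}`
(`<Td>` from 10 to 10^4), 500 generations, 10 replicates per `D`, sampling
every 10 generations, and `Ub = 3.28e-10` — one hundred times the per-bp
rate, so the population-scale mutation supply `A*Ub*Lgenome` is about 14
per generation and the dynamics stay in the clonal-interference regime at
desk scale.

**Two-locus variant.** `run_two_locus()` follows two biallelic loci in the
same compartment structure. Reproduction draws each offspring's haplotype
from the selection-weighted active distribution; with probability `r_rec`
the second-locus allele comes instead from an independently drawn parent.
`r_rec = 0` is complete linkage (identical trajectories for alleles on a
shared founder haplotype); `r_rec = 1` makes the loci evolve as independent
Wright-Fisher marginals. The recombination mechanism is a standard
free-mating approximation; the supplementary model it emulates is not
fully reproduced in the source text, so this component is documented as an
approximation.

## Trajectory statistics

Pooled counts give the naive frequency estimator `f = F/G` (alternate
reads over depth); zero-depth cells are missing, not zero. The
accumulation of diversity in a population is summarized by the sum of
derived allele frequencies `M(t)`; uncovered cells contribute zero with a
warning, since the estimator sums *detected* derived alleles.

`log10 M` typically rises and saturates, and is modelled
phenomenologically as a hyperbola,

```
log10 M(t*) = log10 M(0) + [log10 M]max * t* / (t*_1/2 + t*),
```

with `t*` the time since the first sample. `[log10 M]max` is the
saturation amplitude (how much diversity can accumulate) and `t*_1/2` the
half-time (how fast), converted to generations as `tau_1/2 = t*_1/2 *`
generations-per-day. The fit is nonlinear least squares on the `log10`
scale via BFGS from a deterministic factorial grid of 54 starts —
intercepts at the min/mean/max of the data, amplitudes at 0.5/1/2 times the
observed range, and six log-spaced half-times spanning the sampled window —
keeping the best objective; the half-time is optimized on the log scale to
stay positive. Noiseless self-consistency recovery is at the 10^-6
relative-error level. Residual-bootstrap confidence intervals are
available; their coverage is validated on a densely sampled design
(25 timepoints), because with seven points and three parameters the
residual bootstrap undercovers for standard small-sample reasons.

Three per-trajectory measures capture dynamics over a mutation's sojourn:

* `f_max`, the maximum observed frequency (by default over the first six
  observations, so series of different lengths are comparable);
* `|df|/dtau`, the per-generation magnitude of change between consecutive
  observations;
* the direction ratio `f(tau+dtau)/f(tau)`, computed only where
  `f(tau) > 0` (a later zero yields a ratio of zero; an initial zero is
  undefined and excluded).

Distributions of these measures are compared between cohorts via empirical
survival curves (`S(x)` = fraction of values strictly above `x`) and
two-sample Kolmogorov-Smirnov tests with Benjamini-Hochberg correction
across a batch of comparisons. In simulation studies the seed bank
*contracts* all three distributions as `<Td>` grows. For `f_max` and
`|df|/dtau` the median is a faithful contraction statistic; the direction
ratio contracts toward 1 (frozen dynamics) rather than toward 0, so its
breadth is summarized as the median of `|log ratio|`.

Mutation fates are called with a transparent threshold rule (fixed if the
final observed frequency is at least 0.95; extinct if ever detected at 0.05
and finally at or below 0.01; otherwise segregating), replacing model-based
fate inference; externally produced fate labels can be supplied instead.
`Pr[extinct | detected]` is the extinct fraction among detected mutations.
Pairwise Pearson correlations between simultaneously segregating mutations
(at least three shared timepoints strictly inside (0,1)) provide a
recombination proxy; both `r` and `r^2` are reported, with `r^2` the
conventional comparison scale.

Generation counts for serial-transfer experiments use
`dtau = log2(Nf/Ni)` per transfer; replicate estimates are averaged on the
log2 scale, which is what makes a set of printed per-replicate means
reproducible. The relative log fitness of a mutant against a reference is
`X(t) = log[(Nmut(t)/Nwt(t)) * (Nwt(0)/Nmut(0))]`, natural log by default
(the standard convention for selection-like quantities; the base is an
argument).

## Gene-level parallelism

With `n_i` nonsynonymous mutations in gene `i` of effective nonsynonymous
length `L_i` (mean `Lbar`), the multiplicity is `m_i = n_i * Lbar / L_i`;
under the size-proportional null all genes share `mbar = n_tot / N_genes`.
The genome-wide parallelism score

```
delta_ell = sum_i n_i log(m_i / mbar)
```

is `n_tot` times a Kullback-Leibler divergence, hence nonnegative and zero
only when counts are exactly proportional to lengths; genes with `n_i = 0`
contribute zero (the `n log n -> 0` limit). Significance comes from
permutation (mutations reassigned to genes with probability proportional
to `L_i`), and cohorts of different sizes are compared by subsampling
mutations without replacement to a common total, optionally excluding a
named gene set (a regulon-exclusion control).

Per-gene enrichment uses the Poisson tail `P_i = P(N >= n_i)` at rate
`lambda_i = n_tot L_i / (Lbar N_genes)`, evaluated through the upper
regularized incomplete gamma function. The false-discovery threshold `P*`
is the largest observed P-value at which the expected number of null genes
reaching it (from the Poisson survival curves, respecting the same count
filter), divided by the observed number reaching it, stays at or below
`alpha`. Only genes with at least three mutations across replicate
populations are eligible — the count filter trades sensitivity for power
exactly as in the source methodology — and the total `n_tot` includes all
mutations, with the filter gating only significance testing. A plain
Benjamini-Hochberg alternative is selectable. Effective lengths come from
codon-level site counting under the standard genetic code (substitutions to
stop codons count as nonsynonymous; a trailing stop codon is excluded), or
from a precomputed length table.

Region- and gene-set-level enrichment uses the upper binomial tail with
the region's genome fraction as the success probability, plus a simulated
binomial null for signed between-cohort differences in region fractions.

## Convergence and divergence between cohorts

Whether two cohorts' significant gene sets overlap more (convergence) or
less (divergence) than chance is tested against the exact hypergeometric
null for the intersection of two uniformly random subsets. The magnitude
of divergence among a gene universe `I` uses relative multiplicities
`M_i = m_i / sum(m)` and the mean absolute difference
`<dM> = mean |M_i1 - M_i2|` (bounded by `2/|I|`). The null randomizes the
gene-by-cohort count matrix with both margins fixed, using Patefield's
algorithm (`r2dtable`) — the classical fixed-margin sampler, which draws
from the margin-conditional multivariate hypergeometric distribution; its
sampled table frequencies are validated against exhaustive enumeration
with the exact conditional weights. The observed `<dM>` is standardized as
`Z = (obs - null mean)/null sd`; positive `Z` means divergence, negative
convergence, and both a normal-approximation and an empirical-quantile
p-value are reported. A degenerate fibre (a single admissible table) yields
`Z = NA` with a warning.

Two conventions deserve note. First, the gene universe for a pair of
cohorts is the union of their significant sets, with genes absent from one
cohort entering with count zero; the intersection is a selectable
alternative. Second, when *validating* that `Z` is centred on zero under
shared rates, the universe must be fixed in advance (the shared planted
set, in the synthetic study): selecting the universe through significance
in either cohort biases the observed `<dM>` even under the null.

Genes preferentially enriched in one cohort use the Skellam distribution —
the law of a difference of two independent Poisson counts — with per-gene
rates from each cohort's total and the gene's length share. The pmf is
evaluated in log space with exponentially scaled Bessel functions, and the
two-sided tail `P(|N1 - N2| >= |n1 - n2|)` is controlled with the same
survival-curve false-discovery rule as the Poisson scan.

## The synthetic-data generator

The generator emulates the sampling design of a serial-transfer
evolve-and-resequence experiment: cohorts of strains by transfer regimes,
five replicate populations each, seven sampling timepoints 100 days apart,
pooled sequencing with depth drawn from a shifted negative binomial (mean
100, dispersion 3, minimum 1), binomial read sampling `F ~ Bin(G, f)`, and
a detection floor of 0.01 applied to each mutation's maximum observed
frequency — mutations that never surface are omitted from the observable
table but retained in the ground truth. True trajectories come either from
the simulator or from a parametric surrogate in which each mutation arises
at a uniform time with an exponential selection coefficient and either
sweeps logistically or rises and collapses, the typical fate of a clonal
interference casualty.

Gene-count tables are Poisson with rates proportional to effective length
times a planted multiplier, calibrated to an expected cohort total
`n_tot`. The default planted-enrichment scenario — ten planted genes at a
10x rate among 1,000 — uses `n_tot = 2000`, chosen so the expected planted
count is around 18 for typical gene lengths and stays near 10 at the short
end of the length distribution; that is the operating point the
planted-recovery validation is designed to probe (sensitivity at least
0.9 with false-discovery rate at most 0.05). Divergence scenarios plant
disjoint sets per cohort. Synthetic genomes have log-normal gene lengths
(median 900 bp, sdlog 0.25), valid in-frame coding sequences (ATG start,
no internal stops, TAA stop), alternating strands on one contig, and are
emitted as FASTA plus GFF3 so the annotation readers are exercised
end to end.

What the generator does *not* emulate: sequencing error beyond binomial
counting noise, mapping artefacts, linkage between mutations in the
surrogate model, depth correlation across timepoints, and multi-hit sites.
Passing tests on synthetic data therefore demonstrate the statistical
machinery under the stated observation model, not robustness to the full
messiness of real pooled sequencing.

## Numerical choices and degenerate inputs

* Optimizer: BFGS, relative objective tolerance 10^-12, 54-start grid;
  all-start failure returns a diagnosable fit-failure object, not an error.
* Poisson/binomial tails via `ppois`/`pbinom` upper tails (regularized
  incomplete gamma/beta); the survival-curve threshold search inverts the
  Poisson tail with an upper-tail quantile plus a one-step correction to
  avoid `1 - P` precision loss at tiny `P`.
* Skellam pmf in log space with `besselI(..., expon.scaled = TRUE)`.
* Zero-variance trajectory pairs are skipped (with a message) in the
  correlation scan; `pN/pS` with zero synonymous counts is `NA` with a
  warning, not infinity; zero counts make the relative-fitness measure
  `NA` likewise.
* `c = 0` with `D > 0` is allowed as a permanently inert seed bank, with a
  warning; `c > 0` with `D = 0` is a configuration error; fractional `c`
  counts are rounded with a warning.
* Replicate `r` of a run uses seed `seed + r`; identical seeds give
  bit-identical results, including emitted files.

## Validation studies and their sizes

The test suite validates each operation against independent oracles
(closed forms, exhaustive enumeration, brute-force summation, textbook
formulas) and runs study-level checks at fixed sizes chosen to keep the
suite fast while leaving Monte-Carlo error well inside the tested margins:
neutral fixation probability with 10^4 absorption runs at `A = 100`;
heterozygosity decay `(1 - 1/A)` per generation over 10^4 replicates;
dwell-time mean `D/c` from roughly 2x10^4 samples of one long run; the
reduced-scale dormancy grid described above (40 runs); 100 noiseless and
60 noisy diversity-model recoveries; 100 planted-enrichment datasets, 50
divergence-power datasets, 200 null-Z datasets; and 2x10^4 sampled
fixed-margin tables against exhaustive enumeration at table total 10. The
`scripts/acceptance.R` entry point re-runs the same studies from scratch
and writes the resulting numbers as JSON.

## Known limitations

* The simulator models beneficial mutations only — no deleterious or
  neutral input classes — and constant `A`, `D`, `c`; demographic
  fluctuations between transfers are outside its scope.
* The two-locus recombination mechanism is a free-mating approximation.
* The fate caller is a threshold rule, deliberately simpler than
  model-based inference; trajectories that hover near a threshold are
  sensitive to it.
* Cohort comparisons assume the per-gene effective lengths are shared
  across cohorts (the same genome annotation).
* The multivariate extension of the set-overlap null beyond two cohorts is
  not implemented; pairs are compared with the exact two-set
  hypergeometric.
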