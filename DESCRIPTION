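Package: seedbankevo
Title: Seed-Bank Wright-Fisher Simulation and Molecular Evolution Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-time Wright-Fisher simulation of adapting microbial
    populations structured into active and dormant (seed-bank) compartments,
    together with the statistics used to analyse pooled-sequencing mutation
    trajectories from evolve-and-resequence experiments: allele-frequency
    estimation, a hyperbolic model of diversity accumulation, trajectory
    summary measures and their survival distributions, gene-level parallelism
    via multiplicity and Poisson enrichment with a survival-curve false
    discovery rule, and convergence/divergence statistics based on
    hypergeometric overlap, fixed-margin contingency-table permutation nulls,
    and the Skellam distribution. Includes a synthetic-data generator that
    emulates pooled sequencing of serially transferred populations so the
    whole pipeline can be exercised without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    methods,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
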