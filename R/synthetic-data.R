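# Synthetic inputs with the statistical structure the analysis assumes:
# pooled-sequencing trajectory tables built from true frequency trajectories
# plus binomial read noise, gene catalogs with realistic length variation,
# and gene-by-cohort mutation-count tables with planted enrichment.

#' Specification for the synthetic-data generator
#'
#' Defaults emulate the sampling design of a serial-transfer
# evolve-and-resequence experiment: two strains, 5 replicate populations,
#' 7 sampling timepoints 100 days apart, pooled sequencing at mean depth
#' 100x with a detection floor of order 1e-2.
#'
#' @param strains Strain labels (default `c("wt", "mutant")`).
#' @param regimes Transfer-regime labels (default `"1day"`).
#' @param n_populations Replicate populations per cohort (default 5).
#' @param days Sampling days (default `seq(100, 700, by = 100)`, 7 samples).
#' @param generations_per_day Generations accrued per day (default 3.3,
#'   the 1:10 serial-dilution rate).
#' @param depth_mean Mean sequencing depth (default 100).
#' @param depth_dispersion Negative-binomial size parameter of the depth
#'   model (default 3); depths are shifted to be at least 1.
#' @param detection_floor Minimum observed frequency for a mutation to enter
#'   the observable table (default 0.01, applied to the maximum observed
#'   frequency across timepoints).
#' @param n_mutations Mean number of de novo mutations per population for
#'   the parametric trajectory surrogate (default 30).
#' @param dfe_scale Scale of the exponential distribution of beneficial
#'   effects used by the surrogate (default 0.01).
#' @param n_genes Number of genes in the synthetic genome (default 1000).
#' @param gene_length_meanlog,gene_length_sdlog Log-normal gene-length
#'   parameters in base pairs (default `log(900)` and 0.25).
#' @param n_planted Number of planted enriched genes per cohort (default 10).
#' @param planted_multiplier Rate multiplier of planted genes (default 10).
#' @param planted_disjoint If `TRUE`, each cohort receives its own disjoint
#'   planted set (a divergence scenario); default `FALSE` (shared set).
#' @param n_tot Target total mutation count per cohort for gene-count
#'   generation (default 2000; totals are Poisson around this target).
#'   The default is calibrated so a 10x planted gene of typical length has
#'   an expected count near 18 (around 11 for genes at the short end of the
#'   length distribution), the regime the planted-recovery scenario is
#'   designed to probe.
#' @param seed RNG seed (default 1).
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(strains = c("wt", "mutant"), regimes = "1day",
                           n_populations = 5, days = seq(100, 700, by = 100),
                           generations_per_day = 3.3,
                           depth_mean = 100, depth_dispersion = 3,
                           detection_floor = 0.01, n_mutations = 30,
                           dfe_scale = 0.01, n_genes = 1000,
                           gene_length_meanlog = log(900),
                           gene_length_sdlog = 0.25,
                           n_planted = 10, planted_multiplier = 10,
                           planted_disjoint = FALSE, n_tot = 2000,
                           seed = 1) {
  if (depth_mean < 1) stopf("depth_mean must be at least 1")
  if (planted_multiplier < 1) stopf("planted multipliers must be >= 1")
  if (n_planted > n_genes) stopf("planted set cannot exceed the gene universe")
  structure(
    list(strains = strains, regimes = regimes, n_populations = n_populations,
         days = sort(days), generations_per_day = generations_per_day,
         depth_mean = depth_mean, depth_dispersion = depth_dispersion,
         detection_floor = detection_floor, n_mutations = n_mutations,
         dfe_scale = dfe_scale, n_genes = n_genes,
         gene_length_meanlog = gene_length_meanlog,
         gene_length_sdlog = gene_length_sdlog,
         n_planted = n_planted, planted_multiplier = planted_multiplier,
         planted_disjoint = planted_disjoint, n_tot = n_tot,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# Sampled sequencing depth: shifted negative binomial, always >= 1.
sample_depth <- function(n, spec) {
  1L + stats::rnbinom(n, mu = spec$depth_mean - 1, size = spec$depth_dispersion)
}

# Logistic frequency of a selected allele founded at frequency f0, s per
# generation, tau generations after origin (0 before origin).
logistic_freq <- function(tau, s, f0 = 1e-3) {
  ifelse(tau <= 0, 0, f0 * exp(s * tau) / (1 + f0 * (exp(s * tau) - 1)))
}

#' Generate a synthetic pooled-sequencing trajectory dataset
#'
#' True per-mutation frequency trajectories come either from the seed-bank
#' Wright-Fisher simulator or from a parametric logistic-sweep surrogate
#' (default): each mutation arises at a uniform time with an
#' Exponential(`dfe_scale`) selection coefficient and either sweeps
#' logistically or rises and collapses (a clonal-interference casualty).
#' Observations apply the pooled-sequencing model: depth drawn from the
#' coverage model, alternate reads Binomial(depth, f).  Mutations whose
#' observed frequency never reaches the detection floor are omitted from
#' the observable table but retained in the ground truth.
#'
#' @param spec A [synthetic_spec()].
#' @param catalog Optional [gene_catalog()]; mutations are then assigned to
#'   genes with probability proportional to length.
#' @param truth_model `"logistic"` (default) or `"simulator"`.
#' @param sim_params A [seed_bank_params()] used when
#'   `truth_model = "simulator"`.
#' @return A list with `trajectories` (a [trajectory_matrix()] of observable
#'   rows, frequencies estimated) and `truth` (per-mutation true
#'   trajectories, fates, and generating parameters).
#' @export
generate_trajectory_dataset <- function(spec, catalog = NULL,
                                        truth_model = c("logistic", "simulator"),
                                        sim_params = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  truth_model <- match.arg(truth_model)
  with_seed(spec$seed, {
    gens <- spec$days * spec$generations_per_day
    cohorts <- expand.grid(strain = spec$strains, regime = spec$regimes,
                           pop = seq_len(spec$n_populations),
                           stringsAsFactors = FALSE)
    rows <- list(); truth_rows <- list(); truth_traj <- list()
    for (ci in seq_len(nrow(cohorts))) {
      strain <- cohorts$strain[ci]; regime <- cohorts$regime[ci]
      pop <- sprintf("%s_%s_p%d", strain, regime, cohorts$pop[ci])
      if (truth_model == "simulator") {
        if (is.null(sim_params)) stopf("sim_params required for simulator truth")
        sim <- run_simulation(sim_params, replicate = ci)
        # interpolate the recorded trajectory onto the sampling days
        tf <- vapply(gens, function(g) {
          j <- which.min(abs(sim$sample_gens - g))
          sim$freq[, j]
        }, numeric(nrow(sim$freq)))
        if (is.null(dim(tf))) tf <- matrix(tf, nrow = nrow(sim$freq))
        ids <- rownames(sim$freq)
        s_eff <- sim$mut_effects[ids]
      } else {
        n_mut <- stats::rpois(1, spec$n_mutations)
        ids <- if (n_mut > 0) sprintf("%s_m%03d", pop, seq_len(n_mut)) else character(0)
        s_eff <- stats::rexp(n_mut, 1 / spec$dfe_scale)
        origin <- stats::runif(n_mut, 0, max(gens) * 0.8)
        transient <- stats::runif(n_mut) < 0.6
        peak <- origin + stats::runif(n_mut, 50, 400)
        tf <- t(vapply(seq_len(n_mut), function(m) {
          f <- logistic_freq(gens - origin[m], s_eff[m])
          if (transient[m]) {
            # rise until the peak time, then collapse at the same rate
            fpk <- logistic_freq(peak[m] - origin[m], s_eff[m])
            dec <- logistic_freq(peak[m] - origin[m] - (gens - peak[m]), s_eff[m])
            f <- ifelse(gens > peak[m], pmin(fpk, dec), f)
          }
          f
        }, numeric(length(gens))))
        if (n_mut == 0) tf <- matrix(0, 0, length(gens))
      }
      if (!nrow(tf)) next
      gene_id <- if (!is.null(catalog)) {
        sample(catalog$gene_id, nrow(tf), replace = TRUE,
               prob = catalog$length)
      } else rep(NA_character_, nrow(tf))
      ann <- sample(c("nonsynonymous", "synonymous", "intergenic"),
                    nrow(tf), replace = TRUE, prob = c(0.7, 0.2, 0.1))
      depth <- matrix(sample_depth(length(tf), spec), nrow = nrow(tf))
      alt <- matrix(stats::rbinom(length(tf), as.vector(depth), as.vector(tf)),
                    nrow = nrow(tf))
      fhat <- alt / depth
      detected <- apply(fhat, 1, max) >= spec$detection_floor
      final <- tf[, ncol(tf)]
      fate <- ifelse(final >= 0.95, "fixed",
                     ifelse(apply(tf, 1, max) >= spec$detection_floor &
                              final <= 0.01, "extinct", "segregating"))
      truth_rows[[pop]] <- data.frame(
        mutation_id = ids, population_id = pop, s = as.numeric(s_eff),
        fate = fate, detected = detected, stringsAsFactors = FALSE)
      rownames(tf) <- ids
      truth_traj[[pop]] <- tf
      if (any(detected)) {
        keep <- which(detected)
        rows[[pop]] <- data.frame(
          mutation_id = rep(ids[keep], times = length(gens)),
          population_id = pop, strain = strain, regime = regime,
          gene_id = rep(gene_id[keep], times = length(gens)),
          annotation_class = rep(ann[keep], times = length(gens)),
          day = rep(spec$days, each = length(keep)),
          generations = rep(gens, each = length(keep)),
          alt_count = as.vector(alt[keep, , drop = FALSE]),
          depth = as.vector(depth[keep, , drop = FALSE]),
          stringsAsFactors = FALSE)
      }
    }
    obs <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
           else stats::setNames(data.frame(matrix(ncol = length(TRAJ_COLUMNS),
                                                  nrow = 0)), TRAJ_COLUMNS)
    list(
      trajectories = estimate_frequencies(trajectory_matrix(obs)),
      truth = list(mutations = do.call(rbind, c(truth_rows,
                                                list(make.row.names = FALSE))),
                   trajectories = truth_traj,
                   sample_generations = gens, spec = spec)
    )
  })
}

#' Generate synthetic gene-by-cohort mutation counts with planted enrichment
#'
#' Per cohort (strain x regime), gene counts are Poisson with rate
#' proportional to effective length times the planted multiplier, calibrated
#' so the expected total equals `spec$n_tot`.  Planted gene sets are shared
#' across cohorts by default, or disjoint when `spec$planted_disjoint` (the
#' divergence scenario).
#'
#' @param spec A [synthetic_spec()].
#' @param catalog A [gene_catalog()].
#' @return A list with `counts` (genes x cohorts integer matrix), `planted`
#'   (named list of planted gene ids per cohort), and `spec`.
#' @export
generate_gene_counts <- function(spec, catalog) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(catalog, "gene_catalog"))
  with_seed(spec$seed + 1L, {
    cohorts <- expand.grid(strain = spec$strains, regime = spec$regimes,
                           stringsAsFactors = FALSE)
    cohort_ids <- paste(cohorts$strain, cohorts$regime, sep = "_")
    n_cohort <- length(cohort_ids)
    planted <- list()
    if (spec$n_planted > 0) {
      if (spec$planted_disjoint) {
        pool <- sample(catalog$gene_id, spec$n_planted * n_cohort)
        planted <- split(pool, rep(cohort_ids, each = spec$n_planted))
        planted <- planted[cohort_ids]
      } else {
        shared <- sample(catalog$gene_id, spec$n_planted)
        planted <- stats::setNames(rep(list(shared), n_cohort), cohort_ids)
      }
    } else {
      planted <- stats::setNames(rep(list(character(0)), n_cohort), cohort_ids)
    }
    counts <- sapply(cohort_ids, function(cid) {
      mult <- ifelse(catalog$gene_id %in% planted[[cid]],
                     spec$planted_multiplier, 1)
      w <- catalog$length * mult
      stats::rpois(nrow(catalog), spec$n_tot * w / sum(w))
    })
    rownames(counts) <- catalog$gene_id
    list(counts = counts, planted = planted, spec = spec)
  })
}

#' Generate a synthetic genome (gene catalog, sequences, annotation)
#'
#' Gene lengths are log-normal (rounded to whole codons, minimum 5 codons);
#' sequences are valid in-frame CDSs: an ATG start, random non-stop codons,
#' and a TAA stop.  Genes are laid head-to-tail on one contig with 50 bp
#' spacers, alternating strand.  Deterministic for a given spec seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `catalog` (effective lengths via
#'   [effective_gene_lengths()]), `sequences` (named character CDSs, as
#'   encoded, i.e. already reverse-complemented for minus-strand genes),
#'   `genome` (the contig sequence), and `annotation` (a data frame with
#'   1-based inclusive `start`, `end`, `strand` per gene).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed + 2L, {
    code <- Biostrings::GENETIC_CODE
    sense_codons <- names(code)[code != "*"]
    n <- spec$n_genes
    bp <- stats::rlnorm(n, spec$gene_length_meanlog, spec$gene_length_sdlog)
    n_codons <- pmax(5L, as.integer(round(bp / 3)))
    ids <- sprintf("gene%04d", seq_len(n))
    seqs <- vapply(n_codons, function(k) {
      paste0("ATG",
             paste(sample(sense_codons, k - 2L, replace = TRUE), collapse = ""),
             "TAA")
    }, character(1))
    names(seqs) <- ids
    strand <- rep(c("+", "-"), length.out = n)
    spacer <- strrep("N", 50)
    placed <- ifelse(strand == "+", seqs,
                     vapply(seqs, revcomp, character(1)))
    lens <- nchar(placed)
    starts <- cumsum(c(1, utils::head(lens + 50, -1)))
    genome <- paste(placed, collapse = spacer)
    annotation <- data.frame(
      gene_id = ids, start = starts, end = starts + lens - 1,
      strand = strand, stringsAsFactors = FALSE
    )
    list(catalog = effective_gene_lengths(seqs), sequences = seqs,
         genome = genome, annotation = annotation, spec = spec)
  })
}

# Reverse complement of a DNA string (plain characters).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
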