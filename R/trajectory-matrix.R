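# The trajectory table: one row per mutation x timepoint, carrying pooled
# sequencing counts.  Kept as a long-format data frame with a light class so
# downstream operations can validate their inputs.

TRAJ_COLUMNS <- c("mutation_id", "population_id", "strain", "regime",
                  "gene_id", "annotation_class", "day", "generations",
                  "alt_count", "depth")

#' Construct a mutation trajectory table
#'
#' One row per mutation per timepoint of pooled population sequencing:
#' `alt_count` reads support the derived allele out of `depth` total reads.
#' A `depth` of 0 encodes a timepoint with no coverage (the frequency is then
#' missing), keeping timepoint grids rectangular.
#'
#' @param df A data frame with columns `mutation_id`, `population_id`,
#'   `strain`, `regime`, `gene_id`, `annotation_class` (one of
#'   `"nonsynonymous"`, `"synonymous"`, `"intergenic"`, `"other"`), `day`,
#'   `generations`, `alt_count`, `depth`.
#' @return The validated data frame with class `trajectory_matrix`.
#' @export
trajectory_matrix <- function(df) {
  df <- as.data.frame(df)
  missing_cols <- setdiff(TRAJ_COLUMNS, names(df))
  if (length(missing_cols)) {
    stopf("trajectory table lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  bad <- which(df$alt_count > df$depth)
  if (length(bad)) {
    stopf("alt_count exceeds depth for mutation '%s' (row %d)",
          df$mutation_id[bad[1]], bad[1])
  }
  if (any(df$alt_count < 0) || any(df$depth < 0)) {
    stopf("counts must be nonnegative")
  }
  key <- paste(df$mutation_id, df$population_id, df$day)
  if (anyDuplicated(key)) {
    stopf("duplicated (mutation_id, population_id, day) at row %d",
          anyDuplicated(key))
  }
  class(df) <- c("trajectory_matrix", "data.frame")
  df
}

#' Estimate allele frequencies from pooled counts
#'
#' Fills the naive frequency estimate `f = alt_count / depth` for every
#' covered cell; cells with zero depth are marked missing (`NA`).
#'
#' @param counts A [trajectory_matrix()].
#' @return The table with a `freq` column added.
#' @examples
#' df <- data.frame(mutation_id = "m1", population_id = "p1", strain = "wt",
#'                  regime = "1day", gene_id = "g1",
#'                  annotation_class = "nonsynonymous", day = 100,
#'                  generations = 333, alt_count = 37, depth = 142)
#' estimate_frequencies(trajectory_matrix(df))$freq
#' @export
estimate_frequencies <- function(counts) {
  counts <- trajectory_matrix(counts)
  counts$freq <- ifelse(counts$depth > 0,
                        counts$alt_count / counts$depth, NA_real_)
  counts
}

#' Sum of derived allele frequencies M(t)
#'
#' For each population and timepoint, sums the estimated frequencies of all
#' mutations: `M(t) = sum_m f_pmt`.  Cells without coverage contribute 0
#' (a logged warning is emitted when any are present), since the estimator
#' sums detected derived alleles.
#'
#' @param traj A [trajectory_matrix()] with frequencies estimated (a `freq`
#'   column; [estimate_frequencies()] is applied if absent).
#' @return A data frame with columns `population_id`, `strain`, `regime`,
#'   `day`, `generations`, `M`.
#' @export
sum_derived_frequencies <- function(traj) {
  if (is.null(traj$freq)) traj <- estimate_frequencies(traj)
  if (anyNA(traj$freq)) {
    warnf("%d uncovered cell(s) contribute 0 to M(t)", sum(is.na(traj$freq)))
    traj$freq[is.na(traj$freq)] <- 0
  }
  out <- stats::aggregate(
    freq ~ population_id + strain + regime + day + generations,
    data = traj, FUN = sum
  )
  names(out)[names(out) == "freq"] <- "M"
  out[order(out$population_id, out$day), , drop = FALSE]
}

#' Convert simulator output to a trajectory table
#'
#' Turns the frequency matrix of a [run_simulation()] result into the long
#' trajectory-table format, optionally applying binomial read sampling
#' (see [generate_trajectory_dataset()] for the full observation model).
#' With `depth = NULL` the true frequencies are exported at "infinite" depth:
#' counts are scaled true frequencies at `denom` reads.
#'
#' @param sim A `seedbank_sim` object.
#' @param population_id,strain,regime Metadata labels for the output rows.
#' @param depth Constant sequencing depth for binomial sampling, or `NULL`
#'   for noise-free export.
#' @param denom Read denominator used for noise-free export (default 1e6).
#' @param generations_per_day Conversion used to fill the `day` column
#'   (default 1: days equal generations).
#' @return A [trajectory_matrix()] with a `freq` column.
#' @export
sim_to_trajectories <- function(sim, population_id = "p1", strain = "sim",
                                regime = "sim", depth = NULL, denom = 1e6,
                                generations_per_day = 1) {
  stopifnot(inherits(sim, "seedbank_sim"))
  f <- sim$freq
  if (!nrow(f)) {
    return(estimate_frequencies(trajectory_matrix(
      stats::setNames(data.frame(matrix(ncol = length(TRAJ_COLUMNS), nrow = 0)),
                      TRAJ_COLUMNS))))
  }
  long <- data.frame(
    mutation_id = rep(rownames(f), times = ncol(f)),
    population_id = population_id, strain = strain, regime = regime,
    gene_id = NA_character_, annotation_class = "other",
    day = rep(sim$sample_gens, each = nrow(f)) / generations_per_day,
    generations = rep(sim$sample_gens, each = nrow(f)),
    stringsAsFactors = FALSE
  )
  truth <- as.vector(f)
  if (is.null(depth)) {
    long$depth <- denom
    long$alt_count <- round(truth * denom)
  } else {
    long$depth <- depth
    long$alt_count <- stats::rbinom(length(truth), depth, truth)
  }
  estimate_frequencies(trajectory_matrix(long))
}
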