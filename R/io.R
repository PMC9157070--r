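# File formats: the trajectory TSV dialect, gene catalogs from GFF3 + FASTA
# or a length TSV, gene-set files, JSON run configuration, and writers that
# stamp outputs with a config hash and seed.  Internal coordinates are
# 0-based half-open; conversion happens only at the GFF3 boundary (GFF3 is
# 1-based inclusive).

#' Write a tabular result with a provenance header
#'
#' Writes a TSV preceded by `#`-prefixed provenance lines (config hash,
#' seed, package version), which [read_trajectories()] and friends skip.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param provenance Named list merged into the header.
#' @return `path`, invisibly.
#' @export
write_tsv_provenance <- function(df, path, provenance = list()) {
  prov <- c(list(package = "seedbankevo",
                 hash = fnv1a_hash(paste(utils::capture.output(utils::str(provenance)),
                                         collapse = ""))),
            provenance)
  header <- vapply(names(prov), function(k) {
    sprintf("# %s=%s", k, paste(format(prov[[k]]), collapse = ","))
  }, character(1))
  con <- file(path, open = "wb") # binary keeps Unix newlines on any platform
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a mutation trajectory table
#'
#' Reads the trajectory TSV dialect (header: `mutation_id, population_id,
#' strain, regime, gene_id, annotation_class, day, generations, alt_count,
#' depth`; one row per mutation x timepoint; `#` lines are provenance) and
#' validates it, reporting the offending line for malformed rows.
#'
#' @param path Path to the TSV.
#' @param quiet Suppress the row/population census message (default FALSE).
#' @return A [trajectory_matrix()] with frequencies estimated.
#' @export
read_trajectories <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  skip <- sum(cumprod(startsWith(lines, "#")))
  df <- utils::read.delim(path, skip = skip, stringsAsFactors = FALSE)
  missing_cols <- setdiff(TRAJ_COLUMNS, names(df))
  if (length(missing_cols)) {
    stopf("malformed header in %s: missing %s", path,
          paste(missing_cols, collapse = ", "))
  }
  for (col in c("alt_count", "depth")) {
    v <- df[[col]]
    bad <- which(!is.finite(v) | v != round(v))
    if (length(bad)) {
      stopf("non-integer %s on line %d of %s", col, skip + 1 + bad[1], path)
    }
  }
  bad <- which(df$alt_count > df$depth)
  if (length(bad)) {
    stopf("alt_count > depth on line %d of %s", skip + 1 + bad[1], path)
  }
  out <- estimate_frequencies(trajectory_matrix(df))
  if (!quiet) {
    message(sprintf("read %d rows: %d population(s), %d timepoint(s)",
                    nrow(out), length(unique(out$population_id)),
                    length(unique(out$day))))
  }
  out
}

#' Write a mutation trajectory table
#'
#' @param traj A [trajectory_matrix()].
#' @param path Output path.
#' @param provenance Named list for the provenance header.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(traj, path, provenance = list()) {
  write_tsv_provenance(as.data.frame(traj)[, TRAJ_COLUMNS], path, provenance)
}

#' Read a gene catalog from annotation or a length table
#'
#' Either a GFF3 (CDS features, 1-based inclusive coordinates) plus the
#' genome FASTA — effective nonsynonymous lengths are then computed from the
#' strand-aware extracted coding sequences — or a two-column
#' `gene_id<TAB>length` TSV of precomputed lengths.
#'
#' @param gff3_path Path to a GFF3 annotation (used with `fasta_path`).
#' @param fasta_path Path to the genome FASTA.
#' @param length_tsv Path to a precomputed length table (bypass).
#' @param sets Optional named list of gene-set files (one gene id per line).
#' @return A [gene_catalog()].
#' @export
read_gene_annotation <- function(gff3_path = NULL, fasta_path = NULL,
                                 length_tsv = NULL, sets = list()) {
  set_lists <- lapply(sets, function(p) readLines(p, warn = FALSE))
  if (!is.null(length_tsv)) {
    df <- utils::read.delim(length_tsv, stringsAsFactors = FALSE,
                            comment.char = "#")
    if (ncol(df) < 2) stopf("length TSV must have gene id and length columns")
    return(gene_catalog(df[[1]], df[[2]], sets = set_lists))
  }
  if (is.null(gff3_path) || is.null(fasta_path)) {
    stopf("supply either gff3_path + fasta_path or length_tsv")
  }
  gff <- rtracklayer::import(gff3_path)
  cds <- gff[gff$type == "CDS"]
  if (!length(cds)) stopf("no CDS features in %s", gff3_path)
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*", "", names(genome))
  ids <- cds$ID %||% cds$Name
  if (is.null(ids)) stopf("CDS features lack ID attributes")
  if (anyDuplicated(ids)) {
    # multi-part CDS: concatenate parts in genomic order per gene
    parts <- split(cds, ids)
    seqs <- vapply(parts, function(gr) {
      gr <- gr[order(GenomicRanges::start(gr))]
      s <- paste(vapply(seq_along(gr), function(i) {
        as.character(Biostrings::subseq(
          genome[[as.character(GenomicRanges::seqnames(gr[i]))]],
          GenomicRanges::start(gr[i]), GenomicRanges::end(gr[i])))
      }, character(1)), collapse = "")
      if (as.character(GenomicRanges::strand(gr[1])) == "-") revcomp(s) else s
    }, character(1))
  } else {
    seqs <- vapply(seq_along(cds), function(i) {
      s <- as.character(Biostrings::subseq(
        genome[[as.character(GenomicRanges::seqnames(cds[i]))]],
        GenomicRanges::start(cds[i]), GenomicRanges::end(cds[i])))
      if (as.character(GenomicRanges::strand(cds[i])) == "-") revcomp(s) else s
    }, character(1))
    names(seqs) <- ids
  }
  effective_gene_lengths(seqs, sets = set_lists)
}

#' Write synthetic genome fixtures (FASTA + GFF3)
#'
#' Writes the [generate_genome()] output as a single-contig FASTA and a GFF3
#' with one CDS feature per gene (1-based inclusive coordinates), plus a
#' `gene_id<TAB>length` TSV of the effective lengths.  Output bytes are
#' deterministic for a given genome object.
#'
#' @param genome A [generate_genome()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_genome_fixtures <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "genome.fasta")
  gff3 <- file.path(dir, "genes.gff3")
  lengths <- file.path(dir, "gene_lengths.tsv")
  con <- file(fasta, "wb")
  writeLines(c(">contig1", substring(genome$genome,
                                     seq(1, nchar(genome$genome), 70),
                                     pmin(seq(70, nchar(genome$genome) + 69, 70),
                                          nchar(genome$genome)))), con)
  close(con)
  ann <- genome$annotation
  con <- file(gff3, "wb")
  writeLines(c("##gff-version 3",
               sprintf("contig1\tseedbankevo\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                       ann$start, ann$end, ann$strand, ann$gene_id)), con)
  close(con)
  cat_df <- data.frame(gene_id = genome$catalog$gene_id,
                       length = genome$catalog$length)
  con <- file(lengths, "wb")
  writeLines(c("gene_id\tlength",
               sprintf("%s\t%.6f", cat_df$gene_id, cat_df$length)), con)
  close(con)
  invisible(c(fasta = fasta, gff3 = gff3, lengths = lengths))
}

#' Read a run configuration JSON
#'
#' Stage parameters for the pipeline.  Unknown top-level keys are rejected
#' so typos fail fast.
#'
#' @param path Path to the JSON file.
#' @return A named list of stage parameter lists.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("simulate", "synth", "trajstats", "fitmodel", "parallelism",
             "convergence", "report", "seed", "provenance")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  cfg
}
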