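# Effective nonsynonymous length of a coding sequence: at every codon
# position, the fraction of the 3 possible point substitutions that change
# the encoded amino acid (substitutions creating a stop codon count as
# nonsynonymous, the usual site-counting convention).  Summed over all sites
# this gives L_i, the effective number of nonsynonymous bases of the gene.

BASES <- c("A", "C", "G", "T")

# Per-codon nonsynonymous site counts under the standard (bacterial) code,
# computed once by exhaustive enumeration of all 9 single-base changes.
nonsyn_site_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    code <- Biostrings::GENETIC_CODE
    codons <- names(code)
    out <- stats::setNames(numeric(length(codons)), codons)
    for (cd in codons) {
      aa <- code[[cd]]
      nt <- strsplit(cd, "")[[1]]
      nonsyn <- 0
      for (pos in 1:3) {
        for (b in setdiff(BASES, nt[pos])) {
          alt <- nt
          alt[pos] <- b
          if (code[[paste(alt, collapse = "")]] != aa) nonsyn <- nonsyn + 1
        }
      }
      out[[cd]] <- nonsyn / 3 # 9 substitutions over 3 sites
    }
    tab <<- out
    tab
  }
})

#' Effective nonsynonymous gene lengths from coding sequences
#'
#' For each in-frame coding sequence, sums over codon positions the fraction
#' of the 3 possible point substitutions that are nonsynonymous under the
#' standard genetic code.  A trailing stop codon is allowed and excluded
#' from the length; an internal stop or a length not divisible by 3 is an
#' error naming the gene.
#'
#' @param coding_sequences Named character vector of DNA sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @param sets Optional gene sets passed through to [gene_catalog()].
#' @return A [gene_catalog()] with the computed `L_i`.
#' @examples
#' effective_gene_lengths(c(gene1 = "ATGAAATTTTAA"))
#' @export
effective_gene_lengths <- function(coding_sequences, sets = list()) {
  if (methods::is(coding_sequences, "DNAStringSet")) {
    coding_sequences <- stats::setNames(as.character(coding_sequences),
                                        names(coding_sequences))
  }
  ids <- names(coding_sequences)
  if (is.null(ids)) stopf("coding sequences must be named by gene id")
  tab <- nonsyn_site_table()
  code <- Biostrings::GENETIC_CODE
  L <- vapply(ids, function(g) {
    seqd <- toupper(coding_sequences[[g]])
    if (nchar(seqd) %% 3 != 0) {
      stopf("gene '%s': length %d is not divisible by 3", g, nchar(seqd))
    }
    codons <- substring(seqd, seq(1, nchar(seqd), 3), seq(3, nchar(seqd), 3))
    if (any(!codons %in% names(code))) {
      stopf("gene '%s': non-ACGT codon", g)
    }
    aas <- code[codons]
    if (aas[length(aas)] == "*") {
      codons <- codons[-length(codons)]
      aas <- aas[-length(aas)]
    }
    if (any(aas == "*")) stopf("gene '%s': internal stop codon", g)
    sum(tab[codons])
  }, numeric(1))
  gene_catalog(ids, L, sets = sets)
}
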