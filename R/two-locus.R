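# Two biallelic loci segregating in an active/dormant population.
#
# Haplotype classes: ab, Ab, aB, AB (A and B denote the two focal alleles).
# Each generation applies (1) metabolic exchange with repair, exactly as the
# single-locus simulator, and (2) selection/reproduction with recombination:
# an offspring draws its parent from the selection-weighted active haplotype
# distribution; with probability r_rec it instead draws two such parents
# independently and combines the locus-1 allele of the first with the
# locus-2 allele of the second.

HAPLOTYPES <- c("ab", "Ab", "aB", "AB")
HAS_A <- c(FALSE, TRUE, FALSE, TRUE)
HAS_B <- c(FALSE, FALSE, TRUE, TRUE)

#' Run the two-locus seed-bank simulation with recombination
#'
#' Both focal alleles start on the same founder haplotype (`AB`) at frequency
#' `min(init_freq)`, with the excess of the more common allele placed on the
#' corresponding single-allele haplotype; under `r_rec = 0` and equal initial
#' frequencies the two alleles are completely linked.  Frequencies are
#' reported over the combined active + dormant pool.
#'
#' @param params A [two_locus_params()] object.
#' @param record_interval Generations between recorded samples (default 1).
#' @return A `two_locus_sim` object with the two allele-frequency
#'   trajectories, their Pearson correlation over the recorded samples, and
#'   the haplotype-frequency matrix.
#' @export
run_two_locus <- function(params, record_interval = 1L) {
  stopifnot(inherits(params, "two_locus_params"))
  with_seed(params$seed, {
    A <- params$A; D <- params$D
    p1 <- params$init_freq[1]; p2 <- params$init_freq[2]
    # founder haplotype AB carries both alleles; surplus of the commoner
    # allele rides alone
    fAB <- min(p1, p2)
    hap_freq <- c(ab = 1 - max(p1, p2), Ab = p1 - fAB, aB = p2 - fAB, AB = fAB)
    active <- round(hap_freq * A)
    active[1] <- active[1] + (A - sum(active)) # rounding repair
    dormant <- round(hap_freq * D)
    if (D > 0) dormant[1] <- dormant[1] + (D - sum(dormant))
    w_hap <- exp(HAS_A * params$s[1] + HAS_B * params$s[2])

    record <- function(active, dormant) (active + dormant) / (A + D)
    traj <- list(record(active, dormant))
    for (t in seq_len(params$generations)) {
      # (1) metabolic exchange: exactly c uniform individuals per direction
      if (params$c > 0) {
        n_in <- draw_mvh(active, params$c)
        n_out <- draw_mvh(dormant, params$c)
        active <- active - n_in + n_out
        dormant <- dormant + n_in - n_out
      }
      # (2) selection-weighted reproduction with recombination among actives
      w <- active * w_hap
      if (sum(w) == 0) stopf("active compartment lost all individuals")
      q <- w / sum(w)
      qA <- q[2] + q[4] # selection-weighted allele-1 parent frequency
      qB <- q[3] + q[4]
      recomb <- c((1 - qA) * (1 - qB), qA * (1 - qB), (1 - qA) * qB, qA * qB)
      off <- (1 - params$r_rec) * q + params$r_rec * recomb
      active <- as.numeric(stats::rmultinom(1, A, off))
      if (t %% record_interval == 0L || t == params$generations) {
        traj <- c(traj, list(record(active, dormant)))
      }
    }
    hap <- do.call(rbind, traj)
    colnames(hap) <- HAPLOTYPES
    f1 <- hap[, "Ab"] + hap[, "AB"]
    f2 <- hap[, "aB"] + hap[, "AB"]
    r <- if (stats::sd(f1) > 0 && stats::sd(f2) > 0) stats::cor(f1, f2) else NA_real_
    structure(
      list(freq1 = f1, freq2 = f2, haplotypes = hap,
           correlation = r, r_squared = r^2, params = params),
      class = "two_locus_sim"
    )
  })
}

#' @export
print.two_locus_sim <- function(x, ...) {
  cat("Two-locus seed-bank simulation\n")
  cat(sprintf("  A = %g, D = %g, c = %g, r_rec = %g, %d generations\n",
              x$params$A, x$params$D, x$params$c, x$params$r_rec,
              x$params$generations))
  cat(sprintf("  final frequencies: %.4f, %.4f; trajectory correlation r = %s\n",
              x$freq1[length(x$freq1)], x$freq2[length(x$freq2)],
              format(x$correlation, digits = 4)))
  invisible(x)
}
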