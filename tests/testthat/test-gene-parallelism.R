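# Multiplicity, the parallelism score, Poisson enrichment and the
# survival-curve false-discovery threshold.

test_that("multiplicity rescales counts by relative gene length", {
  expect_equal(multiplicity(4, 900, 900), 4)
  expect_equal(multiplicity(3, 1800, 900), 1.5)
  expect_equal(multiplicity(0, 500, 900), 0)
  expect_error(multiplicity(1, 0, 900), "L_i")
})

test_that("multiplicity conserves the total count", {
  set.seed(3)
  for (i in 1:10) {
    lens <- rlnorm(50, log(900), 0.4)
    n <- rpois(50, 2)
    cat <- gene_catalog(paste0("g", 1:50), lens)
    m <- multiplicity(n, lens, attr(cat, "Lbar"))
    expect_equal(sum(m * lens / attr(cat, "Lbar")), sum(n))
  }
})

test_that("the parallelism score vanishes iff counts match lengths", {
  cat2 <- gene_catalog(c("a", "b"), c(900, 900))
  expect_equal(delta_ell(c(a = 4, b = 0), cat2), 4 * log(2))
  cat3 <- gene_catalog(c("a", "b", "c"), c(300, 600, 900))
  prop <- c(a = 2, b = 4, c = 6) # exactly proportional to length
  expect_equal(delta_ell(prop, cat3), 0, tolerance = 1e-12)
  # nonnegativity: delta_ell = n_tot * KL divergence
  set.seed(6)
  for (i in 1:20) {
    lens <- rlnorm(30, log(900), 0.5)
    catx <- gene_catalog(paste0("g", 1:30), lens)
    n <- rpois(30, 1.5)
    names(n) <- catx$gene_id
    expect_gte(delta_ell(n, catx), -1e-12)
  }
  expect_equal(delta_ell(stats::setNames(numeric(0), character(0)), cat2), 0)
})

test_that("permutation significance flags planted concentration", {
  cat <- make_catalog(50)
  hot <- stats::setNames(c(20, rep(1, 10)), cat$gene_id[1:11])
  res <- delta_ell_permutation(hot, cat, iterations = 300, seed = 2)
  expect_lt(res$p_value, 0.05)
  expect_equal(res$observed, delta_ell(hot, cat))
})

test_that("subsampling the full total reproduces the observed score", {
  cat <- make_catalog(20)
  counts <- stats::setNames(rpois(20, 2) + 1, cat$gene_id)
  obs <- delta_ell(counts, cat)
  sub <- subsample_delta_ell(counts, cat, target_total = sum(counts),
                             iterations = 5, seed = 1)
  expect_true(all(abs(sub - obs) < 1e-12))
  one <- subsample_delta_ell(counts, cat, target_total = 10, iterations = 1,
                             seed = 9)
  expect_identical(one, subsample_delta_ell(counts, cat, target_total = 10,
                                            iterations = 1, seed = 9))
  expect_error(subsample_delta_ell(counts, cat, target_total = 0), "positive")
})

test_that("subsampling shrinks the score of strongly enriched tables", {
  cat <- make_catalog(100)
  planted <- stats::setNames(c(rep(30, 5), rep(1, 40)), cat$gene_id[1:45])
  obs <- delta_ell(planted, cat)
  sub <- subsample_delta_ell(planted, cat, target_total = 60,
                             iterations = 200, seed = 3)
  expect_lt(mean(sub), obs)
})

test_that("regulon exclusion drops the named set before subsampling", {
  cat <- make_catalog(10, sets = list(reg = c("g001", "g002")))
  counts <- stats::setNames(rep(2, 10), cat$gene_id)
  sub <- subsample_delta_ell(counts, cat, target_total = 16, iterations = 2,
                             exclude_set = "reg", seed = 4)
  expect_length(sub, 2)
  expect_error(subsample_delta_ell(counts, cat, 5, exclude_set = "nope"),
               "unknown gene set")
})

test_that("Poisson enrichment P-values match direct term summation", {
  expect_equal(poisson_gene_pvalue(0, 100, 900, 900, 100), 1)
  # lambda = 2, n = 4: 1 - e^-2 (1 + 2 + 2 + 4/3)
  expect_equal(poisson_gene_pvalue(4, 200, 900, 900, 100),
               1 - exp(-2) * (1 + 2 + 2 + 4 / 3), tolerance = 1e-12)
  for (lambda in c(0.5, 2, 7, 20)) {
    for (n in c(0, 1, 3, 10, 50)) {
      expect_lt(abs(poisson_gene_pvalue(n, lambda * 100, 900, 900, 100) -
                      poisson_tail_oracle(n, lambda)), 1e-12)
    }
  }
  p <- vapply(0:10, poisson_gene_pvalue, numeric(1),
              n_tot = 200, L_i = 900, Lbar = 900, N_genes = 100)
  expect_true(all(diff(p) < 0))
})

test_that("the critical threshold spans its vacuous and empty extremes", {
  lambda <- rep(0.5, 100)
  # alpha = 1: every filtered gene is significant
  p <- c(0.2, 0.5, 0.9)
  expect_equal(critical_pvalue(p, lambda, alpha = 1), 0.9)
  # p-values no better than the null tail: nothing passes at alpha = 0.05
  expect_equal(critical_pvalue(c(0.5, 0.9), lambda, alpha = 0.05), 0)
})

test_that("enrichment calls match a brute-force refilter and find planted genes", {
  set.seed(12)
  cat <- make_catalog(300)
  counts <- stats::setNames(rpois(300, 0.5), cat$gene_id)
  counts[1:5] <- counts[1:5] + 12 # planted hot genes
  enr <- gene_enrichment(counts, cat)
  brute <- enr$genes$gene_id[enr$genes$p_value <= enr$p_star & enr$genes$n >= 3]
  expect_setequal(significant_genes(enr), brute)
  expect_true(all(cat$gene_id[1:5] %in% significant_genes(enr)))
  # empty table
  empty <- gene_enrichment(stats::setNames(numeric(0), character(0)), cat)
  expect_length(significant_genes(empty), 0)
  # BH alternative is selectable
  bh <- gene_enrichment(counts, cat, method = "BH")
  expect_true(all(cat$gene_id[1:5] %in% significant_genes(bh)))
})

test_that("binomial region test matches exhaustive pmf summation", {
  expect_equal(region_binomial_test(0, 10, 0.03), 1)
  expect_equal(region_binomial_test(2, 2, 0.5), 0.25)
  for (n_total in c(4, 8, 12)) {
    for (l in c(0.03, 0.3, 0.7)) {
      for (n_region in 0:n_total) {
        oracle <- sum(choose(n_total, n_region:n_total) *
                        l^(n_region:n_total) *
                        (1 - l)^(n_total - (n_region:n_total)))
        expect_equal(region_binomial_test(n_region, n_total, l), oracle,
                     tolerance = 1e-12)
      }
    }
  }
  expect_error(region_binomial_test(3, 2, 0.5), "exceed")
})

test_that("signed region-fraction differences use a binomial null", {
  res <- region_fraction_difference(30, 100, 3, 100, l = 0.03,
                                    iterations = 2000, seed = 5)
  expect_lt(res$p_value, 0.05)
  expect_equal(res$observed_diff, 0.27)
  null <- region_fraction_difference(3, 100, 4, 100, l = 0.03,
                                     iterations = 2000, seed = 5)
  expect_gt(null$p_value, 0.05)
})

test_that("effective lengths count nonsynonymous sites by codon enumeration", {
  # ATG: all 9 substitutions change the amino acid -> 3 nonsyn sites
  expect_equal(effective_gene_lengths(c(g = "ATG"))$length, 3)
  # trailing stop codons are excluded
  expect_equal(effective_gene_lengths(c(g = "ATGTAA"))$length, 3)
  # GGA: third position is 4-fold degenerate and contributes 0
  expect_equal(effective_gene_lengths(c(g = "GGA"))$length, 2)
  # doubling a sequence doubles L_i
  one <- effective_gene_lengths(c(g = "ATGGCT"))$length
  two <- effective_gene_lengths(c(g = "ATGGCTATGGCT"))$length
  expect_equal(two, 2 * one)
  expect_error(effective_gene_lengths(c(bad = "ATGA")), "bad.*divisible")
  expect_error(effective_gene_lengths(c(bad = "ATGTAAATG")), "internal stop")
})
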