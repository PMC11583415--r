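test_that("TMB is the mutation count over the footprint and linear", {
  expect_equal(compute_tmb(0), 0)
  expect_equal(compute_tmb(29348), 29348 / 2934.876451)
  expect_equal(compute_tmb(29348), 9.99974, tolerance = 1e-5)
  # panel mode: same formula with the panel footprint as denominator
  expect_equal(compute_tmb(10, genome_size_mb = 1.139322), 10 / 1.139322)
  # linearity
  expect_equal(compute_tmb(2 * 777), 2 * compute_tmb(777))
  expect_error(compute_tmb(-1), ">= 0")
  expect_error(compute_tmb(5, 0), "> 0")
})

test_that("MSI score calls use inclusive conjunctive thresholds", {
  expect_equal(call_msi_scores(10, 0.4), "MSI")
  expect_equal(call_msi_scores(9.9, 0.9), "MSS")
  expect_equal(call_msi_scores(40, 0.39), "MSS")
  expect_equal(call_msi_scores(NA, NA), "unknown")
  # single-score fallback
  expect_equal(call_msi_scores(12, NA), "MSI")
  expect_equal(call_msi_scores(NA, 0.1), "MSS")
  expect_error(call_msi_scores(-1, 0.5), "non-negative")
  # monotone: raising a score never flips MSI to MSS
  set.seed(40)
  for (i in 1:25) {
    s <- runif(1, 0, 30); m <- runif(1, 0, 1)
    if (call_msi_scores(s, m) == "MSI") {
      expect_equal(call_msi_scores(s + runif(1, 0, 10), m), "MSI")
      expect_equal(call_msi_scores(s, m + runif(1, 0, 1)), "MSI")
    }
  }
})

test_that("panel MSI inference requires an LOF hit in an MMR gene", {
  fs_msh2 <- data.frame(gene = "MSH2", variant_class = "Frame_Shift_Del")
  expect_equal(infer_msi_from_panel(fs_msh2), "MSI")
  mis_mlh1 <- data.frame(gene = "MLH1", variant_class = "Missense_Mutation")
  expect_equal(infer_msi_from_panel(mis_mlh1), "MSS")
  other <- data.frame(gene = "TP53", variant_class = "Nonsense_Mutation")
  expect_equal(infer_msi_from_panel(other), "MSS")
  expect_equal(infer_msi_from_panel(NULL), "MSS")
})

test_that("cytolytic score is the geometric mean with its invariances", {
  expect_equal(cytolytic_score(4, 9), 6)
  expect_equal(cytolytic_score(7, 7), 7)
  expect_equal(cytolytic_score(0, 100), 0)
  # scale equivariance
  expect_equal(cytolytic_score(2 * 3, 2 * 12), 2 * cytolytic_score(3, 12))
  expect_equal(cytolytic_score(0, 5, pseudocount = 1), sqrt(6))
  expect_error(cytolytic_score(-1, 5), "non-negative")
})

test_that("signature means cover the fixed gene lists", {
  mc <- marker_config()
  expect_length(mc$m1m2_genes, 10)
  expect_length(mc$ifng_genes, 10)
  fpkm <- setNames(rep(5, 10), mc$m1m2_genes)
  expect_equal(signature_mean_score(fpkm, mc$m1m2_genes), 5)
  fpkm2 <- setNames(c(10, rep(0, 9)), mc$m1m2_genes)
  expect_equal(signature_mean_score(fpkm2, mc$m1m2_genes), 1)
  incomplete <- setNames(rep(1, 9), setdiff(mc$ifng_genes, "STAT1"))
  expect_error(signature_mean_score(incomplete, mc$ifng_genes), "STAT1")
  expect_error(signature_mean_score(fpkm, character(0)), "empty")
})

test_that("marker scoring over a cohort matrix is consistent per sample", {
  co <- simulate_expression_cohort(cohort_config(groups = c(A = 5, B = 5)),
                                   seed = 8)
  sc <- score_immune_markers(co$fpkm)
  expect_equal(nrow(sc), 10)
  i <- 3
  expect_equal(sc$cytolytic[i],
               sqrt(co$fpkm["GZMA", i] * co$fpkm["PRF1", i]))
  mc <- marker_config()
  expect_equal(sc$ifng[i], mean(co$fpkm[mc$ifng_genes, i]))
})

test_that("Fisher 2x2 p equals full fixed-margin enumeration", {
  got <- fisher_exact_2x2(10, 0, 0, 3)
  expect_equal(got$pval, 1 / 286, tolerance = 1e-9)
  expect_equal(got$odds_ratio, Inf)
  bal <- fisher_exact_2x2(5, 5, 5, 5)
  expect_equal(bal$pval, 1)
  expect_equal(bal$odds_ratio, 1)
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "all-zero")
  set.seed(41)
  for (i in 1:40) {
    repeat {
      cells <- as.vector(stats::rmultinom(1, sample(4:30, 1), rep(0.25, 4)))
      if (sum(cells) > 0) break
    }
    got <- fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])
    want <- brute_force_fisher_p(cells[1], cells[2], cells[3], cells[4])
    expect_equal(got$pval, want, tolerance = 1e-9)
  }
})

test_that("group comparisons use Welch tests, BH, and the N >= 3 rule", {
  # symmetric toy input with exactly equal means: t = 0, p = 1
  v <- data.frame(m = c(1, 2, 3, 1, 2, 3))
  lab <- c("a", "a", "a", "b", "b", "b")
  out <- compare_groups(v, lab)
  expect_equal(out$per_marker$welch_p, 1, tolerance = 1e-12)
  # undersized group: not analysed, never a p-value
  out2 <- compare_groups(data.frame(m = rnorm(5)),
                         c("a", "a", "a", "b", "b"))
  expect_false(out2$per_marker$analysed)
  expect_true(is.na(out2$per_marker$welch_p))
  expect_error(compare_groups(v, rep("a", 6)), "two groups")
  # BH across the family matches the hand-computed step-up
  expect_equal(brute_force_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(42)
  vals <- as.data.frame(matrix(rnorm(20 * 4), 20))
  lab4 <- rep(c("a", "b"), each = 10)
  out3 <- compare_groups(vals, lab4)
  expect_equal(out3$per_marker$bh_q, brute_force_bh(out3$per_marker$welch_p),
               tolerance = 1e-12)
  expect_true(all(out3$per_marker$bh_q >= out3$per_marker$welch_p - 1e-12))
})

test_that("three-group comparisons add ANOVA and Tukey HSD", {
  set.seed(43)
  v <- data.frame(m = c(rnorm(5), rnorm(5) + 3, rnorm(5)))
  lab <- rep(c("a", "b", "c"), each = 5)
  out <- compare_groups(v, lab)
  pm <- out$per_marker
  expect_false(is.na(pm$anova_p))
  expect_lt(pm$anova_p, 0.01)
  tk <- out$tukey$m
  expect_equal(nrow(tk), 3)      # three pairwise contrasts
  expect_lt(tk["b-a", "p adj"], 0.05)
})

test_that("the two-proportion test matches the reported extremes", {
  expect_equal(two_proportion_test(5, 10, 50, 100, correct = FALSE), 1)
  expect_lt(two_proportion_test(10, 67, 4, 301), 1e-4)
  # total separation at n = 20 per arm is overwhelmingly significant, in
  # agreement with the exact binomial enumeration (p = 2/C(40,20))
  p_approx <- two_proportion_test(20, 20, 0, 20)
  expect_lt(p_approx, 1e-7)
  expect_error(two_proportion_test(1, 0, 1, 10), "positive")
  expect_error(two_proportion_test(11, 10, 1, 10), "\\[0, n\\]")
})

test_that("log-rank test matches the risk-set oracle and the N >= 10 rule", {
  set.seed(44)
  times <- c(rexp(12, 0.1), rexp(12, 0.25))
  events <- rbinom(24, 1, 0.8)
  groups <- rep(c("wt", "lof"), each = 12)
  got <- logrank_test(times, events, groups)
  expect_true(got$analysed)
  want <- brute_force_logrank_chisq(times, events, groups == "wt")
  expect_equal(got$chi_sq, want, tolerance = 1e-8)
  expect_equal(got$pval, pchisq(want, 1, lower.tail = FALSE),
               tolerance = 1e-8)
  # identical survival in both groups: chi-square 0, p = 1
  t2 <- rep(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10), 2)
  e2 <- rep(1, 20)
  g2 <- rep(c("a", "b"), each = 10)
  same <- logrank_test(t2, e2, g2)
  expect_equal(same$chi_sq, 0, tolerance = 1e-10)
  expect_equal(same$pval, 1, tolerance = 1e-10)
  # an undersized group is not analysed
  small <- logrank_test(c(t2, 1), c(e2, 1), c(g2, "c"))
  expect_false(small$analysed)
  expect_match(small$reason, "c")
})
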