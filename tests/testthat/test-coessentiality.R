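toy_matrix <- function(m) {
  stopifnot(is.matrix(m))
  if (is.null(rownames(m))) rownames(m) <- sprintf("L%d", seq_len(nrow(m)))
  m
}

test_that("correlations match the closed-form Pearson formula", {
  set.seed(1)
  for (n in c(3, 5, 8)) {
    q <- rnorm(n)
    x <- rnorm(n)
    m <- toy_matrix(cbind(Q = q, X = x))
    rows <- correlate_all(m, "Q")
    hand <- sum((q - mean(q)) * (x - mean(x))) /
      sqrt(sum((q - mean(q))^2) * sum((x - mean(x))^2))
    expect_equal(rows$r[rows$gene == "X"], hand, tolerance = 1e-12)
  }
})

test_that("self-correlation ranks first and negation gives r = -1", {
  set.seed(2)
  q <- rnorm(10)
  m <- toy_matrix(cbind(Q = q, NEG = -q, X = rnorm(10)))
  rows <- correlate_all(m, "Q")
  expect_equal(rows$r[rows$gene == "Q"], 1, tolerance = 1e-12)
  expect_equal(rows$rank[rows$gene == "Q"], 1L)
  expect_equal(rows$r[rows$gene == "NEG"], -1, tolerance = 1e-12)
  expect_equal(rows$rank, seq_len(nrow(rows)))
})

test_that("complete-case handling drops lines and underpowered genes", {
  set.seed(3)
  q <- rnorm(10)
  x <- q + rnorm(10, sd = 0.1)
  x[1:2] <- NA
  sparse <- c(rnorm(2), rep(NA, 8))
  flat <- rep(1, 10)
  m <- toy_matrix(cbind(Q = q, X = x, SPARSE = sparse, FLAT = flat))
  expect_message(rows <- correlate_all(m, "Q"), "dropped")
  expect_false("SPARSE" %in% rows$gene)   # < 3 shared lines
  expect_false("FLAT" %in% rows$gene)     # zero variance
  expect_equal(rows$n_used[rows$gene == "X"], 8L)
  expect_equal(rows$r[rows$gene == "X"], cor(q[-(1:2)], x[-(1:2)]),
               tolerance = 1e-12)
  expect_error(correlate_all(m, "MISSING"), "not present")
})

test_that("permutation p-values are deterministic, bounded and monotone", {
  set.seed(4)
  m <- toy_matrix(matrix(rnorm(30 * 20), 30,
                         dimnames = list(NULL, sprintf("G%02d", 1:20))))
  m[, "G02"] <- m[, "G01"] * 0.9 + rnorm(30, sd = 0.3)
  rows <- correlate_all(m, "G01")
  a1 <- permutation_adjust_correlations(m, "G01", rows, n_perm = 2000, seed = 9)
  a2 <- permutation_adjust_correlations(m, "G01", rows, n_perm = 2000, seed = 9)
  expect_identical(a1, a2)
  expect_true(all(a1$p_perm >= 1 / 2001 & a1$p_perm <= 1))
  # shared null: p is monotone non-increasing in |r|
  o <- order(abs(a1$r), decreasing = TRUE)
  expect_true(all(diff(a1$p_perm[o]) >= 0))
  # an essentially zero correlation sits at the centre of the null
  m0 <- toy_matrix(cbind(Q = c(1, -1, 1, -1, 1, -1), X = c(1, 1, -1, -1, 1, -1),
                         Y = rnorm(6)))
  r0 <- correlate_all(m0, "Q")
  a0 <- permutation_adjust_correlations(m0, "Q", r0, n_perm = 500, seed = 1)
  expect_gt(a0$p_perm[a0$gene == "X"], 0.5)
})

test_that("pooled and per-gene sampled nulls agree with the relabelling rate", {
  # tiny panel: compare the sampled per-gene p against an independent
  # re-estimate with a different seed; both are binomial estimates of the
  # same exhaustive-resampling probability and must agree within the 99% CI.
  set.seed(5)
  m <- toy_matrix(matrix(rnorm(6 * 4), 6,
                         dimnames = list(NULL, c("Q", "A", "B", "C"))))
  rows <- correlate_all(m, "Q")
  n_perm <- 4000
  p1 <- permutation_adjust_correlations(m, "Q", rows, n_perm = n_perm,
                                        seed = 1, strategy = "per_gene")
  p2 <- permutation_adjust_correlations(m, "Q", rows, n_perm = n_perm,
                                        seed = 2, strategy = "per_gene")
  for (g in c("A", "B", "C")) {
    x1 <- p1$p_perm[p1$gene == g]
    x2 <- p2$p_perm[p2$gene == g]
    se <- sqrt(x1 * (1 - x1) / n_perm + x2 * (1 - x2) / n_perm)
    expect_lt(abs(x1 - x2), 2.58 * se + 2 / n_perm)
  }
})

test_that("knee detection finds constructed inflection points", {
  # slope -0.001 for ranks 1..100 then -0.1 afterwards: knee at rank 100
  y <- c(12 - 0.001 * (0:99), 12 - 0.001 * 99 - 0.1 * (1:20))
  ranked <- c(y, -0.5, -1, -1.5)
  thr <- find_inflection(ranked)
  expect_equal(thr$idx_pos, 100L)
  expect_equal(thr$r_pos, y[100])
  # perfectly linear positive segment: ties resolve to the smallest rank
  lin <- c(seq(5, 1, length.out = 50), -1, -2, -3)
  expect_equal(find_inflection(lin)$idx_pos, 1L)
  # mirror symmetry
  pos <- c(12 - 0.001 * (0:99), 12 - 0.001 * 99 - 0.1 * (1:20))
  mirrored <- c(pos, rev(-pos))
  thr2 <- find_inflection(mirrored)
  expect_equal(thr2$idx_neg, length(mirrored) - thr2$idx_pos + 1L)
  expect_equal(thr2$r_neg, -pos[thr2$idx_pos])
  # degenerate sides are flagged
  expect_warning(one_sided <- find_inflection(c(3, 2, 1, -0.5)),
                 "negative threshold undefined")
  expect_true(is.na(one_sided$r_neg))
  expect_error(find_inflection(c(1, 2, 3)), "decreasing")
})

test_that("network calls combine alpha and the inflection thresholds", {
  thr <- structure(list(r_pos = 0.2, r_neg = -0.2, idx_pos = 5L, idx_neg = 9L),
                   class = "inflection_thresholds")
  rows <- data.frame(
    gene = c("a", "b", "c", "d", "e"),
    r = c(0.5, 0.5, 0.2, -0.5, 0.1),
    p_perm = c(0.001, 0.2, 0.001, 0.01, 0.001)
  )
  out <- call_essentiality_network(rows, thr)
  expect_equal(out$call, c("coessential", "none", "none", "antiessential",
                           "none"))
  # r equal to the threshold is not called (strict inequality)
  thr_na <- structure(list(r_pos = NA_real_, r_neg = -0.2, idx_pos = NA,
                           idx_neg = 9L), class = "inflection_thresholds")
  expect_warning(out2 <- call_essentiality_network(rows, thr_na),
                 "no co-essential")
  expect_false(any(out2$call == "coessential"))
})

test_that("the essentiality CSV mirrors the screen table convention", {
  cfg <- tiny_panel_config()
  p <- simulate_dependency_panel(cfg, seed = 31)
  ess <- map_essentiality_network(p$gene_effect, "G0001", n_perm = 500,
                                  seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_essentiality_csv(ess$rows, path)
  back <- read.csv(path)
  expect_named(back, c("GeneName", "Estimate", "P.value", "Perm.adj.p.value",
                       "Rank", "Candidate_inflection"))
  expect_equal(nrow(back), nrow(ess$rows))
})
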