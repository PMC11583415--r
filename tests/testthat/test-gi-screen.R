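test_that("rank-sum test matches hand examples and degenerate inputs", {
  expect_equal(rank_sum_test(c(0.2, 0.4, 0.6), c(0.2, 0.4, 0.6))$pval, 1)
  r <- rank_sum_test(c(0.9, 0.8, 0.7), c(0.1, 0.2, 0.3))
  expect_equal(r$U, 9)
  expect_equal(r$pval, 0.1)  # 2 * 1/C(6,3), maximal separation
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
  expect_equal(rank_sum_test(rep(0.5, 6), rep(0.5, 9))$pval, 1)
})

test_that("exact p equals brute-force enumeration for small no-tie groups", {
  set.seed(10)
  for (i in 1:30) {
    m <- sample(2:7, 1)
    n <- sample(2:7, 1)
    v <- sample(seq_len(40), m + n)   # distinct values: no ties
    x <- v[seq_len(m)] / 40
    y <- v[-seq_len(m)] / 40
    expect_equal(rank_sum_test(x, y)$pval, brute_force_mw_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("large-sample p agrees with the reference implementation", {
  set.seed(11)
  for (i in 1:10) {
    x <- rbeta(25, 2, 2)
    y <- rbeta(40, 2, 3)
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE))$p.value
    expect_equal(rank_sum_test(x, y)$pval, ref, tolerance = 1e-10)
    # with ties
    xt <- round(x, 1); yt <- round(y, 1)
    reft <- suppressWarnings(wilcox.test(xt, yt, exact = FALSE))$p.value
    expect_equal(rank_sum_test(xt, yt)$pval, reft, tolerance = 1e-10)
  }
})

test_that("interaction score follows the stated formula", {
  expect_equal(interaction_score(1, 0.8, 0.2), 0)
  expect_equal(interaction_score(0.3, 0.5, 0.5), 0)
  expect_equal(interaction_score(0.01, 0.8, 0.2), 2 * log2(4))
  # floor keeps zero medians finite
  expect_true(is.finite(interaction_score(0.01, 0, 0.5)))
  expect_equal(interaction_score(0.05, 0, 0), 0)
  expect_error(interaction_score(0, 0.5, 0.2), "\\(0, 1\\]")
  # sign coherence
  expect_gt(interaction_score(0.01, 0.6, 0.2), 0)
  expect_lt(interaction_score(0.01, 0.2, 0.6), 0)
})

make_screen_fixture <- function(seed = 1, n_mut = 4, n_wt = 8, n_genes = 12) {
  set.seed(seed)
  lines <- sprintf("L%02d", seq_len(n_mut + n_wt))
  leth <- matrix(rbeta((n_mut + n_wt) * n_genes, 2, 4),
                 nrow = n_mut + n_wt,
                 dimnames = list(lines, sprintf("G%02d", seq_len(n_genes))))
  groups <- data.frame(
    sample_id = lines, gene = "Q",
    group = c(rep("trans_heterozygous_lof", n_mut), rep("control_wt", n_wt)),
    stringsAsFactors = FALSE
  )
  list(leth = leth, groups = groups)
}

test_that("permutation adjustment is deterministic, bounded and monotone", {
  fx <- make_screen_fixture()
  obs <- setNames(c(0.001, 0.2, 0.5, 1, rep(0.8, 8)), colnames(fx$leth))
  a1 <- permutation_adjust_screen(fx$leth, fx$groups, obs, n_perm = 1000,
                                  seed = 3)
  a2 <- permutation_adjust_screen(fx$leth, fx$groups, obs, n_perm = 1000,
                                  seed = 3)
  expect_identical(a1, a2)
  expect_true(all(a1 >= 1 / 1001 & a1 <= 1))
  # monotone non-decreasing in the observed p-value
  o <- order(obs)
  expect_true(all(diff(a1[o]) >= 0))
  # the least extreme observed p maps to (essentially) 1
  expect_gt(a1[["G04"]], 0.95)
  expect_warning(
    permutation_adjust_screen(fx$leth, fx$groups, obs, n_perm = 10, seed = 1),
    "too small"
  )
})

test_that("per-gene sampled null matches the exhaustive 3v3 relabelling", {
  set.seed(12)
  lines <- sprintf("L%d", 1:6)
  leth <- matrix(rbeta(6 * 2, 2, 2), nrow = 6,
                 dimnames = list(lines, c("G1", "G2")))
  groups <- data.frame(sample_id = lines, gene = "Q",
                       group = c(rep("trans_heterozygous_lof", 3),
                                 rep("control_wt", 3)))
  obs <- vapply(c("G1", "G2"), function(g) {
    rank_sum_test(leth[1:3, g], leth[4:6, g])$pval
  }, numeric(1))
  # exhaustive null over the 20 relabellings
  combs <- combn(6, 3)
  for (g in c("G1", "G2")) {
    null_p <- apply(combs, 2, function(idx) {
      rank_sum_test(leth[idx, g], leth[-idx, g])$pval
    })
    exact_adj <- (1 + sum(null_p <= obs[[g]] + 1e-12)) / (1 + length(null_p))
    sampled <- permutation_adjust_screen(leth, groups, obs[g], n_perm = 4000,
                                         seed = 5, strategy = "per_gene")
    se <- sqrt(exact_adj * (1 - exact_adj) / 4000)
    expect_lt(abs(sampled[[g]] - exact_adj), 2.58 * se + 0.01)
  }
})

test_that("the screen recovers a planted SL partner end to end", {
  cfg <- tiny_panel_config()
  p <- simulate_dependency_panel(cfg, seed = 41)
  scr <- run_gi_screen(p, "G0001", n_perm = 1000, seed = 42)
  planted <- p$truth$gi_pairs$partner_gene
  hit <- scr[scr$gene %in% planted, ]
  expect_true(all(hit$direction == "SL"))
  expect_true(all(hit$interaction_score > 0))
  expect_true(all(hit$adj_pval < 0.05))
  # direction calls respect the invariants
  sl <- scr[scr$direction == "SL", ]
  expect_true(all(sl$mutant_median > sl$control_median))
  expect_true(all(sl$adj_pval < 0.05))
  al <- scr[scr$direction == "AL", ]
  expect_true(all(al$mutant_median < al$control_median))
  # sign coherence of the score when adj_pval < 1
  nz <- scr[scr$adj_pval < 1 & scr$mutant_median != scr$control_median, ]
  expect_true(all(sign(nz$interaction_score) ==
                    sign(nz$mutant_median - nz$control_median)))
  # ordering by score
  expect_true(all(diff(scr$interaction_score) <= 0))
})

test_that("the screen rejects undersized mutant groups", {
  cfg <- tiny_panel_config()
  p <- simulate_dependency_panel(cfg, seed = 43)
  keep <- c(p$truth$lof_lines[1],
            setdiff(rownames(p$lethality), p$truth$lof_lines))
  p$lethality <- p$lethality[keep, ]
  p$gene_effect <- p$gene_effect[keep, ]
  p$mutations <- p$mutations[p$mutations$sample_id %in% keep, ]
  p$copy_number <- p$copy_number[p$copy_number$sample_id %in% keep, ]
  p$annotations <- p$annotations[p$annotations$DepMap_ID %in% keep, ]
  expect_error(run_gi_screen(p, "G0001", n_perm = 100, seed = 1),
               "fewer than 2")
})

test_that("the GI CSV uses the screen-table column convention", {
  cfg <- tiny_panel_config()
  p <- simulate_dependency_panel(cfg, seed = 44)
  scr <- run_gi_screen(p, "G0001", n_perm = 200, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_gi_csv(scr, path)
  back <- read.csv(path)
  expect_named(back, c("GeneNames", "Control_median", "Mutant_median",
                       "Control_sd", "Mutant_sd", "Pval", "log2FC_by_median",
                       "Interaction_score", "Adj_pval", "GI_direction"))
})
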