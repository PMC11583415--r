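# Differential-lethality genetic-interaction screening. Per-gene Mann-Whitney
# rank-sum tests compare knockout lethality probabilities between query-LOF
# and wild-type line groups, a permutation scheme calibrates the p-values,
# and an interaction score combines significance with the log2 fold change of
# the group median lethality probabilities.

# Normal-approximation two-sided Mann-Whitney p with tie correction and
# continuity correction, matching the classic large-sample treatment.
mw_normal_p <- function(U, m, n, pooled, ties = TRUE) {
  mu <- m * n / 2
  tie_term <- 0
  if (ties) {
    nties <- tabulate(match(pooled, unique(pooled)))
    tie_term <- sum(nties^3 - nties) / ((m + n) * (m + n - 1))
  }
  sigma2 <- (m * n / 12) * ((m + n + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  z <- U - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)))
}

#' Two-sided Mann-Whitney U rank-sum test
#'
#' Exact enumeration (via the null Wilcoxon distribution) when both groups
#' have at most 8 observations and there are no ties; otherwise a
#' tie-corrected normal approximation with continuity correction. When every
#' value across both groups is identical the p-value is 1.
#'
#' @param values_lof,values_wt Numeric vectors (NA dropped); both non-empty.
#' @return List with `U` (number of (lof, wt) pairs where the lof value wins)
#'   and `pval`.
#' @export
rank_sum_test <- function(values_lof, values_wt) {
  x <- values_lof[!is.na(values_lof)]
  y <- values_wt[!is.na(values_wt)]
  m <- length(x); n <- length(y)
  if (m == 0L || n == 0L) stop("both groups must be non-empty", call. = FALSE)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  if (length(unique(pooled)) == 1L) {
    return(list(U = U, pval = 1))
  }
  ties <- anyDuplicated(pooled) > 0L
  if (!ties && m <= 8L && n <= 8L) {
    p <- if (U > m * n / 2) {
      2 * pwilcox(U - 1, m, n, lower.tail = FALSE)
    } else {
      2 * pwilcox(U, m, n)
    }
    p <- min(1, p)
  } else {
    p <- mw_normal_p(U, m, n, pooled, ties = ties)
  }
  list(U = U, pval = p)
}

#' Permutation-calibrate screen p-values
#'
#' Builds a pooled empirical null of rank-sum p-values by repeatedly drawing a
#' random gene column from the lethality matrix, shuffling the mutant/control
#' group labels over that gene's complete-case lines, and recording the
#' resulting p-value. Each observed p-value is then assigned the add-one
#' empirical tail probability `(1 + #(null p <= p)) / (1 + n_perm)`, which is
#' monotone non-decreasing in the observed p-value. `strategy = "per_gene"`
#' instead builds a separate label-shuffling null for every gene.
#'
#' @param leth_matrix Numeric line-by-gene matrix of lethality probabilities.
#' @param groups Genotype assignment data frame from
#'   [assign_genotype_groups()]; rows labelled `trans_heterozygous_lof`,
#'   `homozygous_lof` or `heterozygous_lof` form the mutant group and
#'   `control_wt` the control group.
#' @param observed_pvals Named numeric vector of per-gene observed p-values.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param strategy `"pooled"` (default) or `"per_gene"`.
#' @param alpha Used only to warn when `n_perm` cannot resolve it.
#' @return Named numeric vector of adjusted p-values.
#' @export
permutation_adjust_screen <- function(leth_matrix, groups, observed_pvals,
                                      n_perm = 10000, seed = NULL,
                                      strategy = c("pooled", "per_gene"),
                                      alpha = 0.05) {
  strategy <- match.arg(strategy)
  n_perm <- assert_count(n_perm, min = 1)
  if (n_perm + 1 < 1 / alpha) {
    warning("n_perm too small to resolve alpha = ", alpha, call. = FALSE)
  }
  mutant <- groups$sample_id[groups$group %in%
    c("trans_heterozygous_lof", "homozygous_lof", "heterozygous_lof")]
  control <- groups$sample_id[groups$group == "control_wt"]
  if (length(mutant) < 2L || length(control) < 2L) {
    stop("both groups need at least 2 members", call. = FALSE)
  }
  with_local_seed(seed)
  lines_used <- c(mutant, control)
  is_mut <- c(rep(TRUE, length(mutant)), rep(FALSE, length(control)))
  sub <- leth_matrix[lines_used, , drop = FALSE]

  null_p_for <- function(col, lab) {
    v <- sub[, col]
    ok <- !is.na(v)
    lab <- lab[ok]
    if (sum(lab) == 0L || sum(!lab) == 0L) return(NA_real_)
    rank_sum_test(v[ok][lab], v[ok][!lab])$pval
  }

  if (strategy == "pooled") {
    cols <- sample.int(ncol(sub), n_perm, replace = TRUE)
    null_p <- vapply(seq_len(n_perm), function(b) {
      null_p_for(cols[b], sample(is_mut))
    }, numeric(1))
    null_p <- null_p[!is.na(null_p)]
    ns <- sort(null_p)
    cnt_le <- findInterval(observed_pvals, ns)
    adj <- (1 + cnt_le) / (1 + length(ns))
  } else {
    adj <- vapply(names(observed_pvals), function(g) {
      nulls <- vapply(seq_len(n_perm), function(b) {
        null_p_for(g, sample(is_mut))
      }, numeric(1))
      nulls <- nulls[!is.na(nulls)]
      (1 + sum(nulls <= observed_pvals[[g]])) / (1 + length(nulls))
    }, numeric(1))
  }
  setNames(as.numeric(adj), names(observed_pvals))
}

#' Genetic interaction score
#'
#' `-log10(adjusted p) * log2(mutant median / control median)`, with both
#' medians floored at `median_floor` before the ratio so that lethality
#' probabilities of exactly zero remain finite. Equal medians give a score of
#' exactly zero regardless of the p-value.
#'
#' @param adj_pval Adjusted p-value(s) in (0, 1].
#' @param mutant_median,control_median Group median lethality probabilities
#'   in \[0, 1\].
#' @param median_floor Lower clamp for the ratio (default 1e-4).
#' @return Numeric score(s).
#' @export
interaction_score <- function(adj_pval, mutant_median, control_median,
                              median_floor = 1e-4) {
  if (any(adj_pval <= 0 | adj_pval > 1)) {
    stop("adjusted p-values must lie in (0, 1]", call. = FALSE)
  }
  lfc <- ifelse(mutant_median == control_median, 0,
                log2(pmax(mutant_median, median_floor) /
                       pmax(control_median, median_floor)))
  -log10(adj_pval) * lfc
}

#' Run a differential-lethality genetic-interaction screen
#'
#' For every gene in the panel's lethality-probability matrix, compares
#' knockout lethality between query-gene LOF lines and wild-type control
#' lines with a two-sided rank-sum test, permutation-calibrates the p-values,
#' and calls a synthetic-lethal (SL) interaction when the adjusted p-value is
#' below `alpha` and the mutant median lethality exceeds the control median,
#' or an alleviating (AL) interaction for the opposite ordering.
#'
#' @param panel A `dependency_panel` (see [simulate_dependency_panel()] or
#'   [load_depmap_bundle()]).
#' @param query Query gene identifier.
#' @param mode Genotyping mode passed to [assign_genotype_groups()].
#' @param alpha Significance level for direction calls (default 0.05).
#' @param n_perm Permutations for the adjustment (default 10000).
#' @param seed Integer seed.
#' @param context Optional disease label; restricts lines to that annotation
#'   context before grouping.
#' @param strategy Permutation strategy, see [permutation_adjust_screen()].
#' @param median_floor See [interaction_score()].
#' @return Data frame of per-gene screen statistics ordered by decreasing
#'   interaction score.
#' @export
run_gi_screen <- function(panel, query, mode = "trans_het_only", alpha = 0.05,
                          n_perm = 10000, seed = NULL, context = NULL,
                          strategy = "pooled", median_floor = 1e-4) {
  leth <- panel$lethality
  lines <- rownames(leth)
  if (!is.null(context)) {
    ann <- panel$annotations
    lines <- intersect(lines, ann$DepMap_ID[ann$disease == context])
    if (length(lines) == 0L) {
      stop("no lines in context '", context, "'", call. = FALSE)
    }
    leth <- leth[lines, , drop = FALSE]
  }
  groups <- assign_genotype_groups(panel$mutations, panel$copy_number,
                                   lines, query, mode = mode)
  mutant <- groups$sample_id[groups$group %in%
    c("trans_heterozygous_lof", "homozygous_lof", "heterozygous_lof")]
  control <- groups$sample_id[groups$group == "control_wt"]
  if (length(mutant) < 2L) {
    stop("mutant group has fewer than 2 lines",
         if (!is.null(context)) paste0(" in context '", context, "'") else "",
         call. = FALSE)
  }
  if (length(control) < 2L) {
    stop("control group has fewer than 2 lines", call. = FALSE)
  }

  genes <- colnames(leth)
  mut_m <- leth[mutant, , drop = FALSE]
  ctl_m <- leth[control, , drop = FALSE]
  stat1 <- function(f, m) apply(m, 2, f, na.rm = TRUE)
  mutant_median <- stat1(median, mut_m)
  control_median <- stat1(median, ctl_m)
  mutant_sd <- apply(mut_m, 2, sd, na.rm = TRUE)
  control_sd <- apply(ctl_m, 2, sd, na.rm = TRUE)
  pval <- vapply(seq_along(genes), function(j) {
    rank_sum_test(mut_m[, j], ctl_m[, j])$pval
  }, numeric(1))
  names(pval) <- genes

  adj <- permutation_adjust_screen(leth, groups, pval, n_perm = n_perm,
                                   seed = seed, strategy = strategy,
                                   alpha = alpha)
  lfc <- ifelse(mutant_median == control_median, 0,
                log2(pmax(mutant_median, median_floor) /
                       pmax(control_median, median_floor)))
  score <- -log10(adj) * lfc
  direction <- rep("none", length(genes))
  direction[adj < alpha & mutant_median > control_median] <- "SL"
  direction[adj < alpha & mutant_median < control_median] <- "AL"

  out <- data.frame(gene = genes,
                    control_median = control_median,
                    mutant_median = mutant_median,
                    control_sd = control_sd,
                    mutant_sd = mutant_sd,
                    pval = pval,
                    adj_pval = adj,
                    log2fc_by_median = lfc,
                    interaction_score = score,
                    direction = direction,
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(out$interaction_score, decreasing = TRUE), , drop = FALSE]
}

#' Write a genetic-interaction screen table
#'
#' Column names follow the dependency-screen convention (`GeneNames`,
#' `Control_median`, `Mutant_median`, `Control_sd`, `Mutant_sd`, `Pval`,
#' `log2FC_by_median`, `Interaction_score`, `Adj_pval`, `GI_direction`).
#'
#' @param screen Data frame from [run_gi_screen()].
#' @param path Output CSV path.
#' @export
write_gi_csv <- function(screen, path) {
  out <- data.frame(GeneNames = screen$gene,
                    Control_median = screen$control_median,
                    Mutant_median = screen$mutant_median,
                    Control_sd = screen$control_sd,
                    Mutant_sd = screen$mutant_sd,
                    Pval = screen$pval,
                    log2FC_by_median = screen$log2fc_by_median,
                    Interaction_score = screen$interaction_score,
                    Adj_pval = screen$adj_pval,
                    GI_direction = screen$direction)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
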