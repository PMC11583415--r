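# Co-essentiality mapping: ranked Pearson correlations between the query
# gene's fitness profile and every screened gene, a permutation-calibrated
# empirical null, knee-point thresholds on the ranked coefficient curve, and
# co-/anti-essential calls.

#' Correlate the query gene's fitness profile against all genes
#'
#' Pearson correlation coefficients between the query column of a line-by-gene
#' fitness (gene effect) matrix and every gene column, computed on the
#' complete-case set of lines for each pair (lines missing either score are
#' dropped). Genes observed on fewer than `min_lines` shared lines, and genes
#' whose complete-case profile has zero variance, are dropped with a message.
#'
#' @param gene_effect Numeric matrix, lines in rows and genes in columns, with
#'   dimnames; `NA` marks missing scores.
#' @param query Column name of the query gene.
#' @param min_lines Minimum shared lines per pair (default 3).
#' @return Data frame with columns `gene`, `r`, `n_used`, `p_cor`
#'   (two-sided Pearson test p-value) and `rank`, ordered by descending `r`.
#' @export
correlate_all <- function(gene_effect, query, min_lines = 3) {
  stopifnot(is.matrix(gene_effect), !is.null(colnames(gene_effect)))
  if (!query %in% colnames(gene_effect)) {
    stop("query gene '", query, "' not present in the gene effect matrix",
         call. = FALSE)
  }
  qv <- gene_effect[, query]
  if (sum(!is.na(qv)) < min_lines) {
    stop("query gene has fewer than ", min_lines, " non-missing scores",
         call. = FALSE)
  }
  n_used <- colSums(!is.na(gene_effect) & !is.na(qv))
  r <- suppressWarnings(
    as.vector(cor(qv, gene_effect, use = "pairwise.complete.obs"))
  )
  drop <- n_used < min_lines | is.na(r)
  if (any(drop)) {
    message(sum(drop), " gene(s) dropped (fewer than ", min_lines,
            " shared lines or zero variance)")
  }
  genes <- colnames(gene_effect)[!drop]
  r <- r[!drop]
  n_used <- n_used[!drop]
  tstat <- r * sqrt(pmax(n_used - 2, 0)) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p_cor <- 2 * stats::pt(abs(tstat), df = pmax(n_used - 2, 1), lower.tail = FALSE)
  ord <- order(r, decreasing = TRUE)
  out <- data.frame(gene = genes[ord], r = r[ord],
                    n_used = as.integer(n_used[ord]), p_cor = p_cor[ord],
                    stringsAsFactors = FALSE)
  out$rank <- seq_len(nrow(out))
  out
}

#' Permutation-adjust co-essentiality correlations
#'
#' Builds an empirical null of correlation coefficients by correlating the
#' query profile against randomly resampled gene-effect score vectors and
#' assigns each observed coefficient the two-sided add-one empirical p-value
#' `(1 + #(|null r| >= |r|)) / (1 + n_perm)`. The default pooled strategy
#' shares one null distribution across all genes, which makes the p-value a
#' monotone function of `|r|`; `strategy = "per_gene"` instead permutes the
#' query profile against each gene's own complete-case vector.
#'
#' @param gene_effect The matrix passed to [correlate_all()].
#' @param query Query gene name.
#' @param observed Data frame from [correlate_all()].
#' @param n_perm Number of resamples (>= 100).
#' @param seed Integer seed; the null is deterministic given the seed.
#' @param strategy `"pooled"` (default) or `"per_gene"`.
#' @param alpha Significance level used only to warn when `n_perm` cannot
#'   resolve it.
#' @return `observed` with a `p_perm` column added.
#' @export
permutation_adjust_correlations <- function(gene_effect, query, observed,
                                            n_perm = 100000, seed = NULL,
                                            strategy = c("pooled", "per_gene"),
                                            alpha = 0.05) {
  strategy <- match.arg(strategy)
  n_perm <- assert_count(n_perm, min = 100)
  if (1 / (n_perm + 1) > alpha) {
    warning("n_perm too small to resolve alpha = ", alpha, call. = FALSE)
  }
  with_local_seed(seed)
  qv <- gene_effect[, query]
  keep <- !is.na(qv)
  q_cc <- qv[keep]
  if (strategy == "pooled") {
    pool <- gene_effect[!is.na(gene_effect)]
    null_abs <- numeric(n_perm)
    block <- 2000L
    done <- 0L
    while (done < n_perm) {
      b <- min(block, n_perm - done)
      draws <- matrix(sample(pool, length(q_cc) * b, replace = TRUE),
                      nrow = length(q_cc))
      # rare constant resampled vectors give NA correlations; they carry no
      # evidence against the observed coefficient and count as |r| = 0
      nr <- suppressWarnings(abs(as.vector(cor(q_cc, draws))))
      nr[is.na(nr)] <- 0
      null_abs[done + seq_len(b)] <- nr
      done <- done + b
    }
    null_sorted <- sort(null_abs)
    # #(null >= |r|) = n_perm - #(null < |r|)
    cnt_ge <- n_perm - findInterval(abs(observed$r), null_sorted,
                                    left.open = TRUE)
    observed$p_perm <- (1 + cnt_ge) / (1 + n_perm)
  } else {
    p <- numeric(nrow(observed))
    for (i in seq_len(nrow(observed))) {
      g <- observed$gene[i]
      x <- gene_effect[, g]
      cc <- keep & !is.na(x)
      xv <- x[cc]; qq <- qv[cc]
      nulls <- vapply(seq_len(n_perm), function(b) {
        abs(cor(qq, sample(xv)))
      }, numeric(1))
      p[i] <- (1 + sum(nulls >= abs(observed$r[i]))) / (1 + n_perm)
    }
    observed$p_perm <- p
  }
  observed
}

# Knee of a decreasing curve: index maximising perpendicular distance from
# the chord joining the endpoints, after scaling both axes to [0, 1]
# (kneedle-style). Ties and numerically flat curves resolve to index 1.
knee_index <- function(y) {
  n <- length(y)
  if (n < 3L) return(NA_integer_)
  if (abs(y[1] - y[n]) < .Machine$double.eps) return(1L)
  x01 <- (seq_len(n) - 1) / (n - 1)
  y01 <- (y - y[n]) / (y[1] - y[n])
  d <- abs(x01 + y01 - 1) / sqrt(2)
  if (max(d) < 1e-9) return(1L)
  which.max(d)
}

#' Locate inflection (knee) points on the ranked correlation curve
#'
#' The positive and negative segments of the ranked coefficient curve are
#' treated separately. On each segment the knee is the rank index maximising
#' the perpendicular distance from the chord joining the segment's endpoints;
#' the negative segment is mirrored (most negative value first) so the two
#' sides are handled symmetrically.
#'
#' @param ranked_r Numeric vector of correlation coefficients sorted in
#'   decreasing order (as produced by [correlate_all()]).
#' @return List of class `inflection_thresholds` with elements `r_pos`,
#'   `r_neg`, `idx_pos`, `idx_neg` (indices refer to positions in
#'   `ranked_r`). A side with fewer than 3 values is `NA` with a warning.
#' @export
find_inflection <- function(ranked_r) {
  stopifnot(is.numeric(ranked_r))
  if (is.unsorted(rev(ranked_r))) {
    stop("ranked_r must be sorted in decreasing order", call. = FALSE)
  }
  pos <- ranked_r[ranked_r > 0]
  neg <- ranked_r[ranked_r < 0]
  r_pos <- r_neg <- NA_real_
  idx_pos <- idx_neg <- NA_integer_
  if (length(pos) >= 3L) {
    idx_pos <- knee_index(pos)
    r_pos <- pos[idx_pos]
  } else {
    warning("fewer than 3 positive coefficients; positive threshold undefined",
            call. = FALSE)
  }
  if (length(neg) >= 3L) {
    mirrored <- rev(-neg)          # most negative first, made positive
    j <- knee_index(mirrored)
    idx_neg <- length(ranked_r) - j + 1L
    r_neg <- ranked_r[idx_neg]
  } else {
    warning("fewer than 3 negative coefficients; negative threshold undefined",
            call. = FALSE)
  }
  structure(list(r_pos = r_pos, r_neg = r_neg,
                 idx_pos = idx_pos, idx_neg = idx_neg),
            class = "inflection_thresholds")
}

#' Call co-essential and anti-essential genes
#'
#' A gene is co-essential when its permutation-adjusted p-value is below
#' `alpha` and its coefficient lies strictly above the positive-curve
#' inflection threshold; anti-essential when the p-value is below `alpha` and
#' the coefficient lies strictly below the negative-curve threshold.
#'
#' @param rows Data frame from [permutation_adjust_correlations()].
#' @param thresholds An `inflection_thresholds` object.
#' @param alpha Significance level (default 0.05).
#' @return `rows` with a `call` column (`coessential`, `antiessential`,
#'   `none`).
#' @export
call_essentiality_network <- function(rows, thresholds, alpha = 0.05) {
  if (!"p_perm" %in% names(rows)) {
    stop("rows must carry permutation-adjusted p-values (p_perm)", call. = FALSE)
  }
  call <- rep("none", nrow(rows))
  if (is.na(thresholds$r_pos)) {
    warning("positive threshold undefined; no co-essential calls", call. = FALSE)
  } else {
    call[rows$p_perm < alpha & rows$r > thresholds$r_pos] <- "coessential"
  }
  if (is.na(thresholds$r_neg)) {
    warning("negative threshold undefined; no anti-essential calls", call. = FALSE)
  } else {
    call[rows$p_perm < alpha & rows$r < thresholds$r_neg] <- "antiessential"
  }
  rows$call <- call
  rows
}

#' Map the full essentiality network of a query gene
#'
#' Convenience wrapper running [correlate_all()],
#' [permutation_adjust_correlations()], [find_inflection()] and
#' [call_essentiality_network()] in sequence.
#'
#' @inheritParams permutation_adjust_correlations
#' @inheritParams call_essentiality_network
#' @return List with elements `rows` (the annotated correlation table) and
#'   `thresholds`.
#' @export
map_essentiality_network <- function(gene_effect, query, n_perm = 100000,
                                     seed = NULL, alpha = 0.05,
                                     strategy = "pooled") {
  rows <- correlate_all(gene_effect, query)
  rows <- permutation_adjust_correlations(gene_effect, query, rows,
                                          n_perm = n_perm, seed = seed,
                                          strategy = strategy, alpha = alpha)
  thresholds <- find_inflection(rows$r)
  rows <- call_essentiality_network(rows, thresholds, alpha = alpha)
  list(rows = rows, thresholds = thresholds)
}

#' Write an essentiality network table
#'
#' Columns mirror the dependency-screen convention: `GeneName`, `Estimate`,
#' `P.value`, `Perm.adj.p.value`, `Rank`, `Candidate_inflection`.
#'
#' @param rows Annotated table from [map_essentiality_network()]`$rows`.
#' @param path Output CSV path.
#' @export
write_essentiality_csv <- function(rows, path) {
  out <- data.frame(GeneName = rows$gene,
                    Estimate = rows$r,
                    P.value = rows$p_cor,
                    Perm.adj.p.value = rows$p_perm,
                    Rank = rows$rank,
                    Candidate_inflection = rows$call != "none")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
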