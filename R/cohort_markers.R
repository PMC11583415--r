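# Cohort marker scores (TMB, MSI calls, cytolytic / M1-M2 / IFN-gamma
# signatures) and the group-comparison statistics used alongside them.

#' Marker configuration
#'
#' Defaults: whole-genome TMB denominator 2934.876451 Mb (effective genome
#' size), MSIsensor >= 10 and MANTIS >= 0.4 thresholds for an MSI call, the
#' six mismatch-repair genes used for panel-based MSI inference, and the
#' fixed gene lists for the cytolytic (GZMA, PRF1 geometric mean), M1/M2
#' macrophage (10-gene mean) and IFN-gamma (10-gene mean) expression scores.
#'
#' @param genome_size_mb,msisensor_min,mantis_min Numeric overrides.
#' @return List of class `marker_config`.
#' @export
marker_config <- function(genome_size_mb = 2934.876451, msisensor_min = 10,
                          mantis_min = 0.4) {
  assert_number(genome_size_mb, lower = .Machine$double.eps)
  assert_number(msisensor_min, lower = 0)
  assert_number(mantis_min, lower = 0)
  structure(list(
    genome_size_mb = genome_size_mb,
    msisensor_min = msisensor_min,
    mantis_min = mantis_min,
    panel_mmr_genes = c("MLH1", "MLH3", "PMS2", "MSH2", "MSH3", "MSH6"),
    cytolytic_genes = c("GZMA", "PRF1"),
    m1m2_genes = c("CXCL11", "IDO1", "CCL19", "CXCL9", "PLA1A", "LAMP3",
                   "CCR7", "APOL6", "CXCL10", "TNIP3"),
    ifng_genes = c("CCR5", "CXCL10", "CXCL11", "CXCL9", "GZMA", "HLA-DRA",
                   "IDO1", "IFNG", "PRF1", "STAT1")
  ), class = "marker_config")
}

#' Tumour mutation burden per megabase
#'
#' Mutation count divided by the sequencing footprint in megabases: the
#' effective genome size for whole-genome calls, or the panel's exonic
#' coverage for targeted panels.
#'
#' @param n_mutations Non-negative mutation count(s).
#' @param genome_size_mb Footprint in Mb (> 0).
#' @return Mutations per Mb.
#' @export
compute_tmb <- function(n_mutations, genome_size_mb = 2934.876451) {
  if (any(n_mutations < 0)) stop("mutation counts must be >= 0", call. = FALSE)
  if (any(genome_size_mb <= 0)) stop("genome size must be > 0", call. = FALSE)
  n_mutations / genome_size_mb
}

#' Call microsatellite instability from MSIsensor and MANTIS scores
#'
#' MSI when every available score meets its (inclusive) threshold, MSS
#' otherwise, and unknown when neither score is available. The conjunctive
#' rule matches paired-threshold MSI calling; when only one score is present
#' the call falls back to that score alone.
#'
#' @param msisensor,mantis Numeric vectors (NA for missing).
#' @param config A [marker_config()].
#' @return Character vector in `c("MSI", "MSS", "unknown")`.
#' @export
call_msi_scores <- function(msisensor, mantis, config = marker_config()) {
  if (any(msisensor < 0, na.rm = TRUE) || any(mantis < 0, na.rm = TRUE)) {
    stop("MSI scores must be non-negative", call. = FALSE)
  }
  n <- max(length(msisensor), length(mantis))
  msisensor <- rep_len(msisensor, n)
  mantis <- rep_len(mantis, n)
  ok1 <- msisensor >= config$msisensor_min
  ok2 <- mantis >= config$mantis_min
  out <- rep("MSS", n)
  both_na <- is.na(msisensor) & is.na(mantis)
  msi <- (is.na(ok1) | ok1) & (is.na(ok2) | ok2) & !both_na
  out[msi] <- "MSI"
  out[both_na] <- "unknown"
  out
}

#' Infer microsatellite instability from panel mutations
#'
#' MSI when any LOF-class mutation (frameshift indel, nonsense, nonstop) hits
#' one of the configured mismatch-repair genes; MSS otherwise.
#'
#' @param mutations Data frame of one sample's mutations with columns `gene`
#'   and `variant_class`.
#' @param config A [marker_config()].
#' @return `"MSI"` or `"MSS"`.
#' @export
infer_msi_from_panel <- function(mutations, config = marker_config()) {
  if (is.null(mutations) || nrow(mutations) == 0L) return("MSS")
  lof <- classify_variant(mutations$variant_class) == "lof"
  if (any(lof & mutations$gene %in% config$panel_mmr_genes)) "MSI" else "MSS"
}

#' Cytolytic activity score
#'
#' Geometric mean of GZMA and PRF1 expression (FPKM). No pseudocount is
#' added by default, so the score is zero whenever either gene is silent;
#' a pseudocount can be supplied for cohorts with many zero values.
#'
#' @param gzma_fpkm,prf1_fpkm Non-negative expression values.
#' @param pseudocount Added to both values before the product (default 0).
#' @return Numeric score(s).
#' @export
cytolytic_score <- function(gzma_fpkm, prf1_fpkm, pseudocount = 0) {
  if (any(gzma_fpkm < 0) || any(prf1_fpkm < 0)) {
    stop("FPKM values must be non-negative", call. = FALSE)
  }
  sqrt((gzma_fpkm + pseudocount) * (prf1_fpkm + pseudocount))
}

#' Mean expression over a fixed signature gene list
#'
#' @param fpkm Named numeric vector of one sample's expression values.
#' @param gene_list Character vector of signature genes; all must be present.
#' @return Arithmetic mean of the listed genes' expression.
#' @export
signature_mean_score <- function(fpkm, gene_list) {
  if (length(gene_list) == 0L) stop("empty gene list", call. = FALSE)
  missing_genes <- setdiff(gene_list, names(fpkm))
  if (length(missing_genes) > 0L) {
    stop("missing expression for gene(s): ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  }
  mean(fpkm[gene_list])
}

#' Score all configured markers for an expression cohort
#'
#' @param fpkm Numeric gene-by-sample FPKM matrix.
#' @param config A [marker_config()].
#' @return Data frame with one row per sample: `sample_id`, `cytolytic`,
#'   `m1m2`, `ifng`.
#' @export
score_immune_markers <- function(fpkm, config = marker_config()) {
  stopifnot(is.matrix(fpkm))
  needed <- unique(c(config$cytolytic_genes, config$m1m2_genes,
                     config$ifng_genes))
  missing_genes <- setdiff(needed, rownames(fpkm))
  if (length(missing_genes) > 0L) {
    stop("expression matrix lacks gene(s): ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  }
  data.frame(
    sample_id = colnames(fpkm),
    cytolytic = cytolytic_score(fpkm["GZMA", ], fpkm["PRF1", ]),
    m1m2 = colMeans(fpkm[config$m1m2_genes, , drop = FALSE]),
    ifng = colMeans(fpkm[config$ifng_genes, , drop = FALSE]),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the probability-mass rule (the sum of probabilities,
#' under fixed margins, of all tables no more probable than the observed
#' one). The odds ratio reported is the sample odds ratio `(a d) / (b c)`
#' (infinite when `b c = 0` and `a d > 0`); the conditional-MLE odds ratio is
#' returned alongside it.
#'
#' @param a,b,c,d Non-negative integer cell counts (rows = factor 1,
#'   columns = factor 2).
#' @param sided `"two_sided"` (default), `"greater"` or `"less"`.
#' @return List with `pval`, `odds_ratio` (sample) and `odds_ratio_cmle`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d, sided = c("two_sided", "greater", "less")) {
  sided <- match.arg(sided)
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) == 0) stop("all-zero table", call. = FALSE)
  tab <- matrix(as.integer(cells), nrow = 2, byrow = TRUE)
  alt <- switch(sided, two_sided = "two.sided", greater = "greater", less = "less")
  ft <- fisher.test(tab, alternative = alt)
  or <- if (b * c == 0) {
    if (a * d > 0) Inf else NaN
  } else {
    (a * d) / (b * c)
  }
  list(pval = ft$p.value, odds_ratio = or,
       odds_ratio_cmle = unname(ft$estimate))
}

# Welch p-value with a guard for degenerate (zero-variance) groups, where
# t.test() refuses: equal means give t = 0 hence p = 1, unequal means p = 0.
welch_p <- function(x, y) {
  if (sd(x) < .Machine$double.eps && sd(y) < .Machine$double.eps) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  t.test(x, y, var.equal = FALSE)$p.value
}

#' Compare marker values between groups
#'
#' For each marker: a Welch (unequal-variance) t-test between the two groups
#' when both have at least `min_n` samples, with Benjamini-Hochberg
#' correction across the marker family. Markers (or whole comparisons) where
#' a group falls below `min_n` are reported as not analysed rather than as
#' p-values. With more than two groups, a one-way ANOVA and Tukey HSD
#' pairwise tests are computed per marker instead of the Welch test.
#'
#' @param values Data frame or matrix, samples in rows, markers in columns.
#' @param labels Group label per sample (length `nrow(values)`).
#' @param min_n Minimum group size to analyse (default 3).
#' @return List with `per_marker` (data frame `marker`, `n_analysed_groups`,
#'   `welch_p`, `bh_q`, `anova_p`, `analysed`) and `tukey` (named list of
#'   pairwise tables, non-empty only for > 2 groups).
#' @export
compare_groups <- function(values, labels, min_n = 3) {
  values <- as.data.frame(values)
  stopifnot(nrow(values) == length(labels))
  labels <- as.character(labels)
  counts <- table(labels)
  if (length(counts) < 2L) stop("need at least two groups", call. = FALSE)
  usable <- names(counts)[counts >= min_n]
  markers <- colnames(values)
  welch <- anova_p <- rep(NA_real_, length(markers))
  tukey <- list()
  analysed <- rep(length(usable) >= 2L, length(markers))
  if (length(usable) >= 2L) {
    keep <- labels %in% usable
    f <- factor(labels[keep])
    for (i in seq_along(markers)) {
      v <- values[keep, i]
      if (nlevels(f) == 2L) {
        welch[i] <- welch_p(v[f == levels(f)[1]], v[f == levels(f)[2]])
      } else {
        fit <- aov(v ~ f)
        anova_p[i] <- summary(fit)[[1]][["Pr(>F)"]][1]
        tukey[[markers[i]]] <- as.data.frame(TukeyHSD(fit)$f)
      }
    }
  }
  bh <- rep(NA_real_, length(markers))
  if (any(!is.na(welch))) bh[!is.na(welch)] <- p.adjust(welch[!is.na(welch)], "BH")
  if (any(!is.na(anova_p))) bh[!is.na(anova_p)] <- p.adjust(anova_p[!is.na(anova_p)], "BH")
  list(per_marker = data.frame(marker = markers,
                               n_analysed_groups = length(usable),
                               welch_p = welch, bh_q = bh, anova_p = anova_p,
                               analysed = analysed,
                               row.names = NULL, stringsAsFactors = FALSE),
       tukey = tukey)
}

#' Two-proportion equality test
#'
#' Two-sided chi-square test that two binomial proportions are equal, with
#' Yates continuity correction by default.
#'
#' @param k1,n1,k2,n2 Successes and totals for the two samples.
#' @param correct Apply continuity correction (default TRUE).
#' @return Two-sided p-value.
#' @export
two_proportion_test <- function(k1, n1, k2, n2, correct = TRUE) {
  if (n1 <= 0 || n2 <= 0) stop("denominators must be positive", call. = FALSE)
  if (k1 > n1 || k2 > n2 || k1 < 0 || k2 < 0) {
    stop("successes must lie in [0, n]", call. = FALSE)
  }
  suppressWarnings(
    prop.test(c(k1, k2), c(n1, n2), correct = correct)$p.value
  )
}

#' Log-rank test between survival groups
#'
#' Standard log-rank chi-square over pooled risk sets. Comparisons where any
#' group has fewer than `min_cases` cases are reported as not analysed.
#'
#' @param times Positive follow-up times.
#' @param events Event indicators (1/TRUE = event, 0/FALSE = censored).
#' @param groups Group label per case (>= 2 groups).
#' @param min_cases Minimum cases per group to analyse (default 10).
#' @return List with `analysed`, and when analysed `chi_sq` and `pval`.
#' @export
logrank_test <- function(times, events, groups, min_cases = 10) {
  stopifnot(length(times) == length(events), length(times) == length(groups))
  if (any(times <= 0)) stop("times must be positive", call. = FALSE)
  groups <- as.character(groups)
  counts <- table(groups)
  if (length(counts) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(counts < min_cases)) {
    return(list(analysed = FALSE,
                reason = paste0("group(s) below ", min_cases, " cases: ",
                                paste(names(counts)[counts < min_cases],
                                      collapse = ", "))))
  }
  sd_fit <- survival::survdiff(
    survival::Surv(times, as.integer(events)) ~ groups
  )
  chi <- unname(sd_fit$chisq)
  list(analysed = TRUE, chi_sq = chi,
       pval = pchisq(chi, df = length(counts) - 1L, lower.tail = FALSE))
}
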