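# Variant classification and cell-line / case genotype grouping.

#' Variant classes counted as loss-of-function
#'
#' Loss-of-function (LOF) alterations are nonsense mutations, frameshift
#' insertions and deletions, and nonstop mutations. Missense and silent
#' variants are never LOF.
#'
#' @format Character vector of MAF `Variant_Classification` values.
#' @export
lof_variant_classes <- c(
  "Nonsense_Mutation", "Frame_Shift_Ins", "Frame_Shift_Del", "Nonstop_Mutation"
)

.variant_classes <- c(
  lof_variant_classes, "Missense_Mutation", "Silent", "Other"
)

#' Classify variants as loss-of-function
#'
#' @param variant_class Character vector of MAF-style variant classifications.
#' @return Character vector, `"lof"` or `"non_lof"`.
#' @examples
#' classify_variant(c("Nonsense_Mutation", "Missense_Mutation"))
#' @export
classify_variant <- function(variant_class) {
  if (length(variant_class) == 0L) return(character(0))
  bad <- setdiff(unique(variant_class), .variant_classes)
  if (length(bad) > 0L) {
    stop("unknown variant classification(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ifelse(variant_class %in% lof_variant_classes, "lof", "non_lof")
}

#' Assign samples to genotype groups for a query gene
#'
#' Samples with two or more LOF mutations, or one LOF mutation combined with
#' copy-number loss, are trans-heterozygous LOF; one LOF mutation without
#' copy-number loss is heterozygous LOF; samples with no mutation of any class
#' and neutral copy number are wild-type controls; samples carrying only
#' non-LOF (e.g. missense or silent) mutations are excluded. An optional
#' `is_homozygous` flag column in `mutations` marks samples whose LOF
#' mutation affects all alleles; zygosity is never inferred otherwise.
#'
#' @param mutations Data frame with columns `sample_id`, `gene`,
#'   `variant_class` and optionally `is_homozygous` (logical).
#' @param cn Data frame with columns `sample_id`, `gene`, `cn_state`
#'   (one of `deep_loss`, `shallow_loss`, `neutral`, `gain`), or `NULL`
#'   (treated as neutral for all samples).
#' @param samples Character vector of all sample identifiers to assign.
#' @param gene Query gene identifier.
#' @param mode `"trans_het_only"` keeps only trans-heterozygous (and
#'   homozygous) lines in the mutant group and excludes heterozygous lines;
#'   `"all_lof"` keeps heterozygous lines as mutants too.
#' @param cn_loss_is_lof When `TRUE` (patient-cohort rule), deep copy-number
#'   loss alone, without any point mutation, is itself an LOF genotype. The
#'   default (`FALSE`, cell-line rule) requires at least one LOF mutation.
#' @return Data frame with columns `sample_id`, `gene`, `group`.
#' @export
assign_genotype_groups <- function(mutations, cn, samples, gene,
                                   mode = c("trans_het_only", "all_lof"),
                                   cn_loss_is_lof = FALSE) {
  mode <- match.arg(mode)
  assert_flag(cn_loss_is_lof)
  stopifnot(is.character(samples), length(samples) > 0L, !anyNA(samples))
  if (anyDuplicated(samples)) stop("duplicated sample identifiers", call. = FALSE)

  if (is.null(mutations)) {
    mutations <- data.frame(sample_id = character(0), gene = character(0),
                            variant_class = character(0))
  }
  mut <- mutations[mutations$gene == gene, , drop = FALSE]
  if (nrow(mut) > 0L) {
    unknown <- setdiff(unique(mut$sample_id), samples)
    if (length(unknown) > 0L) {
      stop("mutation table contains samples absent from the sample list: ",
           paste(head(unknown, 5L), collapse = ", "), call. = FALSE)
    }
    mut$lof <- classify_variant(mut$variant_class) == "lof"
  }

  cn_state <- setNames(rep("neutral", length(samples)), samples)
  if (!is.null(cn) && nrow(cn) > 0L) {
    cng <- cn[cn$gene == gene, , drop = FALSE]
    cng <- cng[cng$sample_id %in% samples, , drop = FALSE]
    if (anyDuplicated(cng$sample_id)) {
      stop("multiple copy-number states for one (sample, gene)", call. = FALSE)
    }
    cn_state[cng$sample_id] <- as.character(cng$cn_state)
  }
  bad_cn <- setdiff(unique(cn_state), c("deep_loss", "shallow_loss", "neutral", "gain"))
  if (length(bad_cn) > 0L) {
    stop("unknown copy-number state(s): ", paste(bad_cn, collapse = ", "),
         call. = FALSE)
  }

  n_lof <- n_any <- setNames(integer(length(samples)), samples)
  hom <- setNames(logical(length(samples)), samples)
  if (nrow(mut) > 0L) {
    t_any <- table(mut$sample_id)
    n_any[names(t_any)] <- as.integer(t_any)
    t_lof <- table(mut$sample_id[mut$lof])
    n_lof[names(t_lof)] <- as.integer(t_lof)
    if ("is_homozygous" %in% names(mut)) {
      hz <- unique(mut$sample_id[mut$lof & mut$is_homozygous %in% TRUE])
      hom[hz] <- TRUE
    }
  }

  loss <- cn_state %in% c("deep_loss", "shallow_loss")
  group <- character(length(samples))
  group[] <- "excluded"
  group[n_any == 0L & cn_state == "neutral"] <- "control_wt"
  group[n_lof == 1L & !loss] <- "heterozygous_lof"
  group[n_lof >= 2L | (n_lof == 1L & loss)] <- "trans_heterozygous_lof"
  if (cn_loss_is_lof) {
    group[n_lof == 0L & n_any == 0L & cn_state == "deep_loss"] <- "homozygous_lof"
  }
  group[hom] <- "homozygous_lof"
  if (mode == "trans_het_only") {
    group[group == "heterozygous_lof"] <- "excluded"
  }

  data.frame(sample_id = samples, gene = gene, group = group,
             stringsAsFactors = FALSE)
}

#' Select cancer contexts eligible for genetic-interaction screening
#'
#' A context is screened when at least `min_pct_mutated` percent of its cohort
#' samples carry a query-gene mutation, at least `min_pct_lof` percent of
#' those mutations are LOF, and at least `min_lines` dependency-screened cell
#' lines are available.
#'
#' @param context_summary Data frame with columns `context`, `n_samples`,
#'   `n_mutated_samples`, `n_mutations`, `n_lof_mutations`.
#' @param line_counts Named integer vector mapping context to the number of
#'   available cell lines (contexts absent from it count as zero lines).
#' @param min_pct_mutated,min_pct_lof Percent thresholds (inclusive).
#' @param min_lines Minimum number of cell lines (inclusive).
#' @return Data frame with per-context percentages, line counts and a
#'   `selected` flag.
#' @export
select_screening_contexts <- function(context_summary, line_counts,
                                      min_pct_mutated = 10, min_pct_lof = 25,
                                      min_lines = 10) {
  req <- c("context", "n_samples", "n_mutated_samples", "n_mutations",
           "n_lof_mutations")
  missing_cols <- setdiff(req, names(context_summary))
  if (length(missing_cols) > 0L) {
    stop("context_summary is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cs <- context_summary
  if (any(cs$n_samples < 0 | cs$n_mutations < 0 | cs$n_mutated_samples < 0 |
          cs$n_lof_mutations < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  zero <- cs$n_samples == 0
  if (any(zero)) {
    warning("context(s) with zero samples excluded: ",
            paste(cs$context[zero], collapse = ", "), call. = FALSE)
  }
  pct_mut <- ifelse(zero, NA_real_, 100 * cs$n_mutated_samples / cs$n_samples)
  pct_lof <- ifelse(cs$n_mutations == 0, NA_real_,
                    100 * cs$n_lof_mutations / cs$n_mutations)
  n_lines <- rep(0L, nrow(cs))
  hit <- cs$context %in% names(line_counts)
  n_lines[hit] <- as.integer(line_counts[cs$context[hit]])
  selected <- !is.na(pct_mut) & !is.na(pct_lof) &
    pct_mut >= min_pct_mutated & pct_lof >= min_pct_lof & n_lines >= min_lines
  data.frame(context = cs$context,
             pct_samples_mutated = pct_mut,
             pct_mutations_lof = pct_lof,
             n_cell_lines = n_lines,
             selected = selected,
             stringsAsFactors = FALSE)
}
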