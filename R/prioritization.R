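# Candidate prioritisation: GI prediction tiers from screen statistics, drug
# tractability groups from bucket annotations, and combined priority classes.

#' Default GI tier thresholds
#'
#' Tier I: adjusted p < 0.01, |log2 fold change| > 2, and a group median
#' lethality probability above 0.5 in at least one group. Tier II relaxes the
#' p threshold to 0.05; tier III additionally drops the median condition.
#' All comparisons are strict.
#'
#' @return List of per-tier thresholds.
#' @export
tier_thresholds <- function() {
  list(
    tier1 = list(p_max = 0.01, log2fc_min = 2, median_min = 0.5),
    tier2 = list(p_max = 0.05, log2fc_min = 2, median_min = 0.5),
    tier3 = list(p_max = 0.05, log2fc_min = 2, median_min = NA_real_)
  )
}

#' Assign GI prediction tiers
#'
#' Vectorised over candidates; the strictest satisfied tier is returned.
#' The median condition is evaluated on the larger of the two group medians
#' (`median_rule = "max_median"`, the default); `median_rule = "either"`
#' accepts a pre-computed logical instead via `median_ok`.
#'
#' @param adj_pval,log2fc,control_median,mutant_median Screen statistics.
#' @param thresholds From [tier_thresholds()].
#' @param median_rule `"max_median"` (default) applies the tier I/II median
#'   floor to `max(control_median, mutant_median)`.
#' @param median_ok Optional logical vector overriding the median condition.
#' @return Character vector in `c("I", "II", "III", "none")`.
#' @export
assign_gi_tier <- function(adj_pval, log2fc, control_median, mutant_median,
                           thresholds = tier_thresholds(),
                           median_rule = c("max_median", "either"),
                           median_ok = NULL) {
  median_rule <- match.arg(median_rule)
  if (anyNA(adj_pval) || anyNA(log2fc)) {
    stop("adj_pval and log2fc must not contain NA", call. = FALSE)
  }
  if (is.null(median_ok)) {
    if (median_rule == "either") {
      stop("median_rule = 'either' requires median_ok", call. = FALSE)
    }
    med_hi <- pmax(control_median, mutant_median)
    med1 <- med_hi > thresholds$tier1$median_min
    med2 <- med_hi > thresholds$tier2$median_min
  } else {
    med1 <- med2 <- median_ok
  }
  afc <- abs(log2fc)
  tier <- rep("none", length(adj_pval))
  tier[adj_pval < thresholds$tier3$p_max & afc > thresholds$tier3$log2fc_min] <- "III"
  tier[adj_pval < thresholds$tier2$p_max & afc > thresholds$tier2$log2fc_min & med2] <- "II"
  tier[adj_pval < thresholds$tier1$p_max & afc > thresholds$tier1$log2fc_min & med1] <- "I"
  tier
}

#' Assign drug tractability groups from bucket annotations
#'
#' Buckets 1-3 (approved or clinical-phase small molecules / antibodies) map
#' to group I, buckets 4-6 to group II, buckets 7-9 to group III; a missing
#' bucket maps to `"none"`. An explicit override group, when supplied, wins
#' and is reported with a message (manual re-classifications, e.g. a target
#' with active drug-development programmes not yet reflected in the buckets).
#'
#' @param bucket Integer vector in 1..9 or `NA`.
#' @param override_group Optional character vector (`NA` for no override).
#' @return Character vector in `c("I", "II", "III", "none")`.
#' @export
assign_drug_group <- function(bucket, override_group = NULL) {
  if (any(!is.na(bucket) & (bucket < 1 | bucket > 9))) {
    stop("tractability buckets must lie in 1..9", call. = FALSE)
  }
  grp <- rep("none", length(bucket))
  grp[!is.na(bucket) & bucket <= 3] <- "I"
  grp[!is.na(bucket) & bucket >= 4 & bucket <= 6] <- "II"
  grp[!is.na(bucket) & bucket >= 7] <- "III"
  if (!is.null(override_group)) {
    ov <- !is.na(override_group)
    if (any(ov)) {
      bad <- setdiff(unique(override_group[ov]), c("I", "II", "III", "none"))
      if (length(bad) > 0L) {
        stop("invalid override group(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
      }
      message(sum(ov), " drug-group override(s) applied")
      grp[ov] <- override_group[ov]
    }
  }
  grp
}

#' Combine GI tier and drug group into a priority class
#'
#' Class A = tier I with drug group I; B = tier I with group II; C = tier I
#' with group III or no tractability; D = tier II or III with any drug group;
#' candidates without a GI tier get no class.
#'
#' @param gi_tier,drug_group Character vectors in `c("I","II","III","none")`.
#' @return Character vector in `c("A", "B", "C", "D", "none")`.
#' @export
assign_priority_class <- function(gi_tier, drug_group) {
  ok <- c("I", "II", "III", "none")
  if (any(!gi_tier %in% ok) || any(!drug_group %in% ok)) {
    stop("tiers and groups must be one of I, II, III, none", call. = FALSE)
  }
  cls <- rep("none", length(gi_tier))
  cls[gi_tier %in% c("II", "III")] <- "D"
  cls[gi_tier == "I"] <- "C"
  cls[gi_tier == "I" & drug_group == "II"] <- "B"
  cls[gi_tier == "I" & drug_group == "I"] <- "A"
  cls
}

#' Prioritise genetic-interaction candidates
#'
#' Joins a screen table with per-gene tractability buckets and appends the GI
#' tier, drug tractability group and priority class.
#'
#' @param screen Data frame from [run_gi_screen()].
#' @param tractability Data frame with columns `gene`, `bucket` and
#'   optionally `override_group`. Genes absent from it get no drug group.
#' @param thresholds From [tier_thresholds()].
#' @return `screen` with columns `gi_tier`, `drug_group`, `priority_class`.
#' @export
prioritize_candidates <- function(screen, tractability = NULL,
                                  thresholds = tier_thresholds()) {
  screen$gi_tier <- assign_gi_tier(screen$adj_pval, screen$log2fc_by_median,
                                   screen$control_median, screen$mutant_median,
                                   thresholds = thresholds)
  bucket <- rep(NA_integer_, nrow(screen))
  override <- rep(NA_character_, nrow(screen))
  if (!is.null(tractability) && nrow(tractability) > 0L) {
    idx <- match(screen$gene, tractability$gene)
    bucket <- tractability$bucket[idx]
    if ("override_group" %in% names(tractability)) {
      override <- as.character(tractability$override_group[idx])
    }
  }
  screen$drug_group <- assign_drug_group(bucket, override)
  screen$priority_class <- assign_priority_class(screen$gi_tier,
                                                 screen$drug_group)
  screen
}

#' Read a drug tractability table
#'
#' Plain TSV with at least `gene` and `bucket` columns (the minimal per-gene
#' bucket snapshot of a tractability pipeline export); an optional
#' `override_group` column carries manual re-classifications.
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_tractability_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "bucket") %in% names(df))) {
    stop("tractability table must have 'gene' and 'bucket' columns",
         call. = FALSE)
  }
  df$bucket <- as.integer(df$bucket)
  df
}
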