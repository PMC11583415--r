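# Seeded generators for DepMap-like dependency panels and expression cohorts
# with planted ground truth. These emulate the structure of public dependency
# screen releases (gene-effect and lethality-probability matrices, MAF-style
# mutations, copy number, line annotations) so every downstream stage can be
# exercised and benchmarked without downloads.

#' Simulation configuration for a dependency panel
#'
#' Defaults describe the reference benchmark panel: 200 cell lines by 2000
#' genes, 40 query-LOF lines, 2% values missing completely at random, a small
#' set of co-essential partners planted at |rho| = 0.8, and synthetic-lethal
#' partners planted for 25% of the gene universe with mean lethality
#' probability 0.8 in LOF lines versus 0.2 in wild-type lines.
#'
#' @param n_lines,n_genes Panel dimensions.
#' @param n_lof_lines Number of lines carrying query-gene LOF genotypes
#'   (must be < `n_lines`).
#' @param missing_rate Fraction of matrix entries set to `NA`, in \[0, 1).
#' @param query_gene Query gene identifier (must be in the gene universe).
#' @param planted_coessential Data frame `gene_a`, `gene_b`, `rho` with
#'   `rho` in (-1, 1); partner identifiers must be distinct across all
#'   planted lists.
#' @param planted_gi Data frame `query_gene`, `partner_gene`, `lof_mean`,
#'   `wt_mean` with means in (0, 1) and `lof_mean != wt_mean`.
#' @param cancer_types Disease labels assigned uniformly to lines.
#' @param non_lof_fraction Fraction of non-LOF lines given a missense
#'   query-gene mutation (these lines are excluded from screens; default 0).
#' @param concentration Beta concentration for lethality probabilities
#'   (default 10).
#' @param line_offset_sd Standard deviation of per-line gene-effect offsets
#'   (default 0.25).
#' @param msi_fraction Fraction of lines annotated MSI (default 0.2).
#' @param seed Default seed used by the generator when none is passed.
#' @return List of class `sim_config`.
#' @export
simulation_config <- function(n_lines = 200, n_genes = 2000, n_lof_lines = 40,
                              missing_rate = 0.02, query_gene = NULL,
                              planted_coessential = NULL, planted_gi = NULL,
                              cancer_types = c("COAD/READ", "STAD", "UCEC"),
                              non_lof_fraction = 0, concentration = 10,
                              line_offset_sd = 0.25, msi_fraction = 0.2,
                              seed = NULL) {
  n_lines <- assert_count(n_lines, min = 4)
  n_genes <- assert_count(n_genes, min = 2)
  n_lof_lines <- assert_count(n_lof_lines, min = 2)
  assert_number(missing_rate, lower = 0, upper = 1 - 1e-9)
  assert_number(non_lof_fraction, lower = 0, upper = 1)
  assert_number(concentration, lower = 1e-6)
  assert_number(msi_fraction, lower = 0, upper = 1)
  if (n_lof_lines >= n_lines) {
    stop("n_lof_lines must be smaller than n_lines", call. = FALSE)
  }
  genes <- sprintf("G%04d", seq_len(n_genes))
  query_gene <- query_gene %||% genes[1]
  if (!query_gene %in% genes) {
    stop("query gene outside the gene universe", call. = FALSE)
  }
  if ((is.null(planted_coessential) || is.null(planted_gi)) && n_genes < 40) {
    stop("default planted lists need n_genes >= 40; supply explicit lists",
         call. = FALSE)
  }
  if (is.null(planted_coessential)) {
    planted_coessential <- data.frame(
      gene_a = query_gene,
      gene_b = genes[2:9],
      rho = c(rep(0.8, 5), rep(-0.8, 3)),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(planted_gi)) {
    n_sl <- max(1L, round(0.25 * n_genes))
    start <- min(n_genes - n_sl + 1L, max(10L, n_genes %/% 4))
    planted_gi <- data.frame(
      query_gene = query_gene,
      partner_gene = genes[seq(start, length.out = n_sl)],
      lof_mean = 0.8, wt_mean = 0.2,
      stringsAsFactors = FALSE
    )
  }
  planted <- c(planted_coessential$gene_b, planted_gi$partner_gene)
  if (anyDuplicated(planted)) {
    stop("planted partner genes must be distinct across planted lists",
         call. = FALSE)
  }
  all_named <- c(planted, planted_coessential$gene_a, planted_gi$query_gene)
  outside <- setdiff(all_named, genes)
  if (length(outside) > 0L) {
    stop("planted gene(s) outside the universe: ",
         paste(head(outside, 5L), collapse = ", "), call. = FALSE)
  }
  if (query_gene %in% planted) {
    stop("the query gene cannot be its own planted partner", call. = FALSE)
  }
  if (any(abs(planted_coessential$rho) >= 1) || any(planted_coessential$rho == 0)) {
    stop("planted rho must lie in (-1, 0) or (0, 1)", call. = FALSE)
  }
  if (any(planted_gi$lof_mean <= 0 | planted_gi$lof_mean >= 1 |
          planted_gi$wt_mean <= 0 | planted_gi$wt_mean >= 1)) {
    stop("planted GI group means must lie in (0, 1)", call. = FALSE)
  }
  if (any(planted_gi$lof_mean == planted_gi$wt_mean)) {
    stop("planted GI effects need lof_mean != wt_mean", call. = FALSE)
  }
  structure(list(
    n_lines = n_lines, n_genes = n_genes, n_lof_lines = n_lof_lines,
    missing_rate = missing_rate, query_gene = query_gene, genes = genes,
    planted_coessential = planted_coessential, planted_gi = planted_gi,
    cancer_types = cancer_types, non_lof_fraction = non_lof_fraction,
    concentration = concentration, line_offset_sd = line_offset_sd,
    msi_fraction = msi_fraction, seed = seed
  ), class = "sim_config")
}

beta_shapes <- function(mean, conc) {
  list(a = mean * conc, b = (1 - mean) * conc)
}

#' Simulate a DepMap-like dependency panel
#'
#' Generates paired line-by-gene gene-effect and lethality-probability
#' matrices with planted structure and records the ground truth. Background
#' gene-effect scores are standard normal with per-line offsets; each planted
#' co-essential pair is built from a shared component so that the population
#' correlation equals the requested `rho`. Lethality probabilities are Beta
#' draws whose per-gene mean is a bimodal mixture (a minority of broadly
#' essential genes near 0.85, the rest below 0.4); planted GI partners use
#' `lof_mean` in LOF-labelled lines and `wt_mean` elsewhere. LOF lines carry
#' two LOF mutation records for the query gene (a trans-heterozygous
#' genotype); all other lines have neutral copy number and, by default, no
#' query-gene mutations. Output is deterministic given the seed.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed (overrides `config$seed`).
#' @return List of class `dependency_panel` with elements `gene_effect`,
#'   `lethality`, `mutations`, `copy_number`, `annotations`, `truth` and
#'   `query`.
#' @export
simulate_dependency_panel <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% config$seed
  with_local_seed(seed)
  n <- config$n_lines
  G <- config$n_genes
  genes <- config$genes
  lines <- sprintf("ACH-%06d", seq_len(n))

  lof_lines <- sort(sample.int(n, config$n_lof_lines))
  is_lof <- seq_len(n) %in% lof_lines

  # gene effect: per-line offset + unit normal noise
  offsets <- rnorm(n, 0, config$line_offset_sd)
  ge <- matrix(rnorm(n * G), nrow = n, dimnames = list(lines, genes)) + offsets

  # planted co-essential pairs share a component calibrated to rho; anchor
  # genes are drawn without line offsets so the calibration is exact
  pc <- config$planted_coessential
  for (a in unique(pc$gene_a)) ge[, a] <- rnorm(n)
  for (i in seq_len(nrow(pc))) {
    rho <- pc$rho[i]
    ge[, pc$gene_b[i]] <- rho * ge[, pc$gene_a[i]] +
      sqrt(1 - rho^2) * rnorm(n)
  }

  # lethality probabilities: bimodal gene-level means, Beta noise
  essential <- runif(G) < 0.15
  gene_mean <- ifelse(essential, runif(G, 0.7, 0.95), runif(G, 0.02, 0.4))
  conc <- config$concentration
  leth <- matrix(NA_real_, n, G, dimnames = list(lines, genes))
  for (j in seq_len(G)) {
    sh <- beta_shapes(gene_mean[j], conc)
    leth[, j] <- rbeta(n, sh$a, sh$b)
  }
  gi <- config$planted_gi
  for (i in seq_len(nrow(gi))) {
    shl <- beta_shapes(gi$lof_mean[i], conc)
    shw <- beta_shapes(gi$wt_mean[i], conc)
    col <- gi$partner_gene[i]
    leth[is_lof, col] <- rbeta(sum(is_lof), shl$a, shl$b)
    leth[!is_lof, col] <- rbeta(sum(!is_lof), shw$a, shw$b)
  }

  if (config$missing_rate > 0) {
    ge[runif(n * G) < config$missing_rate] <- NA
    leth[runif(n * G) < config$missing_rate] <- NA
  }

  # mutations: two LOF records per LOF line (trans-heterozygous); optional
  # missense-only lines that downstream grouping excludes
  lof_classes <- sample(lof_variant_classes, 2L * length(lof_lines),
                        replace = TRUE)
  mutations <- data.frame(
    sample_id = rep(lines[lof_lines], each = 2L),
    gene = config$query_gene,
    variant_class = lof_classes,
    protein_change = NA_character_,
    stringsAsFactors = FALSE
  )
  if (config$non_lof_fraction > 0) {
    wt_idx <- which(!is_lof)
    n_mis <- round(config$non_lof_fraction * length(wt_idx))
    if (n_mis > 0) {
      mis <- sample(wt_idx, n_mis)
      mutations <- rbind(mutations, data.frame(
        sample_id = lines[mis], gene = config$query_gene,
        variant_class = "Missense_Mutation", protein_change = NA_character_,
        stringsAsFactors = FALSE
      ))
    }
  }

  copy_number <- data.frame(sample_id = lines, gene = config$query_gene,
                            cn_state = "neutral", stringsAsFactors = FALSE)

  annotations <- data.frame(
    DepMap_ID = lines,
    stripped_cell_line_name = sprintf("LINE%04d", seq_len(n)),
    disease = sample(config$cancer_types, n, replace = TRUE),
    disease_subtype = "",
    MSI_status = ifelse(runif(n) < config$msi_fraction, "MSI", "MSS"),
    stringsAsFactors = FALSE
  )

  truth <- list(
    coessential_pairs = pc,
    gi_pairs = cbind(gi, direction = ifelse(gi$lof_mean > gi$wt_mean,
                                            "SL", "AL"),
                     effect_size = gi$lof_mean - gi$wt_mean),
    lof_lines = lines[lof_lines],
    marker_effects = NULL
  )

  structure(list(gene_effect = ge, lethality = leth, mutations = mutations,
                 copy_number = copy_number, annotations = annotations,
                 truth = truth, query = config$query_gene),
            class = "dependency_panel")
}

#' Configuration for a synthetic expression cohort
#'
#' @param groups Named integer vector of group sizes (>= 2 groups, each
#'   >= 3 samples).
#' @param n_genes Number of background genes in addition to the configured
#'   marker signature genes.
#' @param planted_fc Data frame `gene`, `group`, `fc` of fold changes (> 0)
#'   applied to the named group's mean expression.
#' @param msi_fraction Named numeric vector of per-group MSI fractions
#'   (recycled; default 0.2 for every group).
#' @param median_survival Named numeric vector of per-group median survival
#'   times (months; recycled; default 24).
#' @param seed Default seed.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(groups = c(WT = 50, LOF = 50), n_genes = 200,
                          planted_fc = NULL, msi_fraction = 0.2,
                          median_survival = 24, seed = NULL) {
  if (length(groups) < 2L || is.null(names(groups))) {
    stop("groups must be a named vector with at least two groups", call. = FALSE)
  }
  if (any(groups < 3)) {
    stop("every group needs at least 3 samples", call. = FALSE)
  }
  if (!is.null(planted_fc)) {
    if (any(planted_fc$fc <= 0)) {
      stop("planted fold changes must be positive", call. = FALSE)
    }
    if (any(!planted_fc$group %in% names(groups))) {
      stop("planted_fc refers to unknown group(s)", call. = FALSE)
    }
  }
  structure(list(groups = groups, n_genes = assert_count(n_genes, min = 0),
                 planted_fc = planted_fc,
                 msi_fraction = rep_len(msi_fraction, length(groups)),
                 median_survival = rep_len(median_survival, length(groups)),
                 seed = seed),
            class = "cohort_config")
}

#' Simulate an expression cohort with clinical annotations
#'
#' FPKM values are log-normal around per-gene baselines (so strictly
#' non-negative); planted fold changes multiply the affected group's mean.
#' The clinical table carries group labels, MSIsensor/MANTIS scores drawn on
#' either side of the MSI calling thresholds according to the per-group MSI
#' fraction, and exponential survival times with ~30% censoring.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed (overrides `config$seed`).
#' @return List of class `expression_cohort` with `fpkm` (gene x sample
#'   matrix), `clinical` (data frame) and `truth`.
#' @export
simulate_expression_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  seed <- seed %||% config$seed
  with_local_seed(seed)
  mc <- marker_config()
  marker_genes <- unique(c(mc$cytolytic_genes, mc$m1m2_genes, mc$ifng_genes))
  genes <- c(marker_genes,
             if (config$n_genes > 0) sprintf("BG%04d", seq_len(config$n_genes)))
  planted_genes <- unique(config$planted_fc$gene)
  genes <- unique(c(genes, planted_genes))
  n_total <- sum(config$groups)
  samples <- sprintf("S%04d", seq_len(n_total))
  group <- rep(names(config$groups), times = config$groups)

  baseline <- rnorm(length(genes), mean = 2, sd = 1)
  names(baseline) <- genes
  meanlog <- matrix(baseline, nrow = length(genes), ncol = n_total,
                    dimnames = list(genes, samples))
  if (!is.null(config$planted_fc)) {
    for (i in seq_len(nrow(config$planted_fc))) {
      g <- config$planted_fc$gene[i]
      grp <- config$planted_fc$group[i]
      meanlog[g, group == grp] <- meanlog[g, group == grp] +
        log(config$planted_fc$fc[i])
    }
  }
  fpkm <- matrix(rlnorm(length(genes) * n_total, meanlog = meanlog,
                        sdlog = 0.5),
                 nrow = length(genes), dimnames = list(genes, samples))

  msi_p <- rep(config$msi_fraction, times = config$groups)
  is_msi <- runif(n_total) < msi_p
  msisensor <- ifelse(is_msi, runif(n_total, 10, 40), runif(n_total, 0, 5))
  mantis <- ifelse(is_msi, runif(n_total, 0.4, 0.8), runif(n_total, 0, 0.3))
  med_surv <- rep(config$median_survival, times = config$groups)
  time <- rexp(n_total, rate = log(2) / med_surv)
  event <- rbinom(n_total, 1, 0.7)

  clinical <- data.frame(sample_id = samples, group = group,
                         MSIsensor = msisensor, MANTIS = mantis,
                         os_months = time, os_event = event,
                         stringsAsFactors = FALSE)
  truth <- list(planted_fc = config$planted_fc, msi = is_msi)
  structure(list(fpkm = fpkm, clinical = clinical, truth = truth),
            class = "expression_cohort")
}
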