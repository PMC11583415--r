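# Configuration-driven end-to-end runs: load a panel, genotype, select
# screening contexts, map the essentiality network, run per-context GI
# screens, prioritise, and write a reproducible report bundle.

#' Build (or validate) a pipeline configuration
#'
#' @param panel_dir Directory holding a DepMap-dialect bundle (see
#'   [write_depmap_bundle()]).
#' @param query_gene Query gene identifier (defaults to the bundle's
#'   recorded query).
#' @param output_dir Where report tables are written.
#' @param seed Master seed (mandatory); per-stage seeds are derived from it.
#' @param contexts Disease contexts to consider in addition to the pooled
#'   pan-cancer screen; defaults to every context present in the
#'   annotations.
#' @param tractability_path Optional tractability TSV.
#' @param mode,alpha,n_perm_correlation,n_perm_screen Analysis settings.
#' @param min_pct_mutated,min_pct_lof,min_lines Context-selection thresholds.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(panel_dir, query_gene = NULL, output_dir,
                            seed, contexts = NULL, tractability_path = NULL,
                            mode = "trans_het_only", alpha = 0.05,
                            n_perm_correlation = 10000, n_perm_screen = 10000,
                            min_pct_mutated = 10, min_pct_lof = 25,
                            min_lines = 10) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  if (!dir.exists(panel_dir)) {
    stop("panel directory not found: ", panel_dir, call. = FALSE)
  }
  if (!is.null(tractability_path) && !file.exists(tractability_path)) {
    stop("tractability file not found: ", tractability_path, call. = FALSE)
  }
  structure(list(panel_dir = panel_dir, query_gene = query_gene,
                 output_dir = output_dir, seed = as.integer(seed),
                 contexts = contexts, tractability_path = tractability_path,
                 mode = mode, alpha = alpha,
                 n_perm_correlation = n_perm_correlation,
                 n_perm_screen = n_perm_screen,
                 min_pct_mutated = min_pct_mutated,
                 min_pct_lof = min_pct_lof, min_lines = min_lines),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

context_summary_from_panel <- function(panel, query) {
  ann <- panel$annotations
  mut <- panel$mutations[panel$mutations$gene == query, , drop = FALSE]
  mut$lof <- classify_variant(mut$variant_class) == "lof"
  mut$context <- ann$disease[match(mut$sample_id, ann$DepMap_ID)]
  contexts <- sort(unique(ann$disease))
  do.call(rbind, lapply(contexts, function(cx) {
    in_cx <- ann$disease == cx
    m <- mut[mut$context == cx, , drop = FALSE]
    data.frame(context = cx,
               n_samples = sum(in_cx),
               n_mutated_samples = length(unique(m$sample_id)),
               n_mutations = nrow(m),
               n_lof_mutations = sum(m$lof),
               stringsAsFactors = FALSE)
  }))
}

#' Run the full genetic-network pipeline
#'
#' Stages: load the panel; summarise per-context mutation burden and select
#' screening contexts; map the query's essentiality network; run the
#' pan-cancer GI screen and one screen per selected context (contexts that
#' fail selection, or whose groups are too small, are skipped with a logged
#' reason); prioritise candidates against the tractability table; write all
#' tables plus a manifest with checksums to the output directory. Per-stage
#' seeds are derived from the master seed so the run is reproducible
#' end-to-end.
#'
#' @param config A `pipeline_config` or the path of a YAML file.
#' @return List of class `report_bundle` with the essentiality table,
#'   per-context GI tables, the priority table, the context-selection table
#'   and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  panel <- load_depmap_bundle(config$panel_dir)
  query <- config$query_gene %||% panel$query
  if (is.null(query)) stop("query gene not specified", call. = FALSE)
  log_msg <- function(...) message("[ginet] ", ...)

  log_msg("context selection")
  cs <- context_summary_from_panel(panel, query)
  line_counts <- table(panel$annotations$disease)
  selection <- select_screening_contexts(
    cs, setNames(as.integer(line_counts), names(line_counts)),
    min_pct_mutated = config$min_pct_mutated,
    min_pct_lof = config$min_pct_lof, min_lines = config$min_lines
  )
  contexts <- selection$context[selection$selected]
  if (!is.null(config$contexts)) {
    contexts <- intersect(contexts, config$contexts)
  }
  skipped <- setdiff(selection$context, contexts)
  for (cx in skipped) log_msg("context skipped (selection thresholds): ", cx)

  log_msg("essentiality network")
  ess <- map_essentiality_network(
    panel$gene_effect, query,
    n_perm = config$n_perm_correlation,
    seed = derive_seed(config$seed, "coessentiality"),
    alpha = config$alpha
  )

  screens <- list()
  run_one <- function(cx) {
    ctx_arg <- if (identical(cx, "pan-cancer")) NULL else cx
    tryCatch(
      run_gi_screen(panel, query, mode = config$mode, alpha = config$alpha,
                    n_perm = config$n_perm_screen,
                    seed = derive_seed(config$seed, paste0("gi:", cx)),
                    context = ctx_arg),
      error = function(e) {
        log_msg("screen skipped for ", cx, ": ", conditionMessage(e))
        NULL
      }
    )
  }
  for (cx in c("pan-cancer", contexts)) {
    log_msg("GI screen: ", cx)
    screens[[cx]] <- run_one(cx)
  }
  screens <- Filter(Negate(is.null), screens)
  if (length(screens) == 0L) stop("no screen could be run", call. = FALSE)

  log_msg("prioritisation")
  tract <- if (!is.null(config$tractability_path)) {
    read_tractability_tsv(config$tractability_path)
  } else NULL
  priority <- do.call(rbind, lapply(names(screens), function(cx) {
    pr <- prioritize_candidates(screens[[cx]], tract)
    cbind(context = cx, pr)
  }))

  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$output_dir, name)
  write_essentiality_csv(ess$rows, out("essentiality_network.csv"))
  for (cx in names(screens)) {
    write_gi_csv(screens[[cx]],
                 out(paste0("gi_screen_", gsub("[^A-Za-z0-9]+", "_", cx), ".csv")))
  }
  write.csv(priority, out("priority_table.csv"), row.names = FALSE)
  write.csv(selection, out("context_selection.csv"), row.names = FALSE)

  files <- list.files(config$output_dir, full.names = TRUE)
  manifest <- data.frame(
    file = basename(files),
    md5 = as.character(tools::md5sum(files)),
    stringsAsFactors = FALSE
  )
  manifest_meta <- c(
    sprintf("package_version: %s",
            as.character(utils::packageVersion("ginet"))),
    sprintf("seed: %d", config$seed),
    sprintf("query_gene: %s", query),
    sprintf("r_version: %s", R.version.string)
  )
  writeLines(c(manifest_meta, "", paste(manifest$md5, manifest$file)),
             out("MANIFEST.txt"))

  structure(list(essentiality = ess, screens = screens, priority = priority,
                 selection = selection, manifest = manifest,
                 output_dir = config$output_dir),
            class = "report_bundle")
}
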