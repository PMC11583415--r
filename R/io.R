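# DepMap-dialect readers and writers. Matrix CSVs use a leading DepMap_ID
# column and "SYMBOL (ENTREZID)" gene headers; mutations follow a minimal
# MAF-style TSV; annotations follow the sample_info.csv convention.

gene_header <- function(genes) {
  sprintf("%s (%d)", genes, seq_along(genes))
}

strip_gene_header <- function(headers) {
  sub(" \\(\\d+\\)$", "", headers)
}

write_matrix_csv <- function(m, path) {
  df <- data.frame(DepMap_ID = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("DepMap_ID", gene_header(colnames(m)))
  write.csv(df, path, row.names = FALSE)
}

read_matrix_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "DepMap_ID") {
    stop("matrix file ", basename(path), " must start with a DepMap_ID column",
         call. = FALSE)
  }
  genes <- strip_gene_header(names(df)[-1])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0L) {
    stop("duplicated gene column(s) in ", basename(path), ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(df$DepMap_ID, genes)
  storage.mode(m) <- "double"
  m
}

#' Write a dependency panel as a DepMap-dialect file bundle
#'
#' Emits `gene_effect.csv` and `lethality.csv` (DepMap_ID rows, gene columns
#' headed `SYMBOL (ENTREZID)`), `mutations.tsv` (MAF-style columns
#' `Hugo_Symbol`, `Variant_Classification`, `Tumor_Sample_Barcode`),
#' `copy_number.tsv`, `sample_info.csv`, and the planted ground truth as
#' plain CSVs.
#'
#' @param panel A `dependency_panel`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_depmap_bundle <- function(panel, dir) {
  stopifnot(inherits(panel, "dependency_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_csv(panel$gene_effect, file.path(dir, "gene_effect.csv"))
  write_matrix_csv(panel$lethality, file.path(dir, "lethality.csv"))
  maf <- data.frame(Hugo_Symbol = panel$mutations$gene,
                    Variant_Classification = panel$mutations$variant_class,
                    Tumor_Sample_Barcode = panel$mutations$sample_id,
                    stringsAsFactors = FALSE)
  write.table(maf, file.path(dir, "mutations.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(panel$copy_number, file.path(dir, "copy_number.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.csv(panel$annotations, file.path(dir, "sample_info.csv"),
            row.names = FALSE)
  if (!is.null(panel$truth)) {
    write.csv(panel$truth$coessential_pairs,
              file.path(dir, "truth_coessential.csv"), row.names = FALSE)
    write.csv(panel$truth$gi_pairs, file.path(dir, "truth_gi.csv"),
              row.names = FALSE)
    writeLines(panel$truth$lof_lines, file.path(dir, "truth_lof_lines.txt"))
  }
  writeLines(panel$query, file.path(dir, "query_gene.txt"))
  invisible(dir)
}

#' Load a DepMap-dialect file bundle into a dependency panel
#'
#' The inverse of [write_depmap_bundle()]; also accepts externally prepared
#' files following the same dialect. Matrices are aligned on their shared
#' line identifiers; mismatched line sets, duplicated gene headers, and
#' missing MAF columns are errors.
#'
#' @param dir Directory containing the bundle, or a named list of paths
#'   (`gene_effect`, `lethality`, `mutations`, `copy_number`, `annotations`).
#' @return A `dependency_panel` (with `truth` when truth files are present).
#' @export
load_depmap_bundle <- function(dir) {
  paths <- if (is.list(dir)) dir else list(
    gene_effect = file.path(dir, "gene_effect.csv"),
    lethality = file.path(dir, "lethality.csv"),
    mutations = file.path(dir, "mutations.tsv"),
    copy_number = file.path(dir, "copy_number.tsv"),
    annotations = file.path(dir, "sample_info.csv")
  )
  for (p in unlist(paths)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  ge <- read_matrix_csv(paths$gene_effect)
  leth <- read_matrix_csv(paths$lethality)
  if (!setequal(rownames(ge), rownames(leth)) ||
      !setequal(colnames(ge), colnames(leth))) {
    stop("gene-effect and lethality matrices cover different lines or genes",
         call. = FALSE)
  }
  leth <- leth[rownames(ge), colnames(ge), drop = FALSE]
  if (any(leth < 0 | leth > 1, na.rm = TRUE)) {
    stop("lethality probabilities outside [0, 1]", call. = FALSE)
  }

  maf <- read.delim(paths$mutations, stringsAsFactors = FALSE)
  need <- c("Hugo_Symbol", "Variant_Classification", "Tumor_Sample_Barcode")
  miss <- setdiff(need, names(maf))
  if (length(miss) > 0L) {
    stop("mutation table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  mutations <- data.frame(sample_id = maf$Tumor_Sample_Barcode,
                          gene = maf$Hugo_Symbol,
                          variant_class = maf$Variant_Classification,
                          protein_change = NA_character_,
                          stringsAsFactors = FALSE)

  cn <- read.delim(paths$copy_number, stringsAsFactors = FALSE)
  ann <- read.csv(paths$annotations, stringsAsFactors = FALSE)
  if (!"DepMap_ID" %in% names(ann)) {
    stop("annotation file lacks a DepMap_ID column", call. = FALSE)
  }
  bad <- setdiff(unique(c(mutations$sample_id, cn$sample_id)), ann$DepMap_ID)
  if (length(bad) > 0L) {
    stop("mutation/copy-number samples absent from annotations: ",
         paste(head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  message("loaded panel: ", nrow(ge), " lines x ", ncol(ge), " genes")

  truth <- NULL
  if (!is.list(dir)) {
    tc <- file.path(dir, "truth_coessential.csv")
    tg <- file.path(dir, "truth_gi.csv")
    if (file.exists(tc) && file.exists(tg)) {
      truth <- list(coessential_pairs = read.csv(tc, stringsAsFactors = FALSE),
                    gi_pairs = read.csv(tg, stringsAsFactors = FALSE),
                    lof_lines = {
                      lf <- file.path(dir, "truth_lof_lines.txt")
                      if (file.exists(lf)) readLines(lf) else NULL
                    })
    }
  }
  query <- NULL
  if (!is.list(dir) && file.exists(file.path(dir, "query_gene.txt"))) {
    query <- readLines(file.path(dir, "query_gene.txt"))[1]
  }
  structure(list(gene_effect = ge, lethality = leth, mutations = mutations,
                 copy_number = cn, annotations = ann, truth = truth,
                 query = query),
            class = "dependency_panel")
}
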