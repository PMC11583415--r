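# Enriched-term clustering: hypergeometric over-representation of gene sets,
# Jaccard similarity between terms, hierarchical clustering, and
# gap-statistic selection of the number of term groups.

#' Build a gene-set collection
#'
#' @param sets Named list of character vectors (term id -> genes); every set
#'   must be non-empty and ids unique.
#' @param names Optional named character vector of human-readable term names.
#' @return List of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, names = NULL) {
  if (is.null(base::names(sets)) || anyDuplicated(base::names(sets))) {
    stop("sets must be a uniquely named list", call. = FALSE)
  }
  if (any(lengths(sets) == 0L)) {
    stop("gene sets must be non-empty", call. = FALSE)
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  structure(list(sets = sets, term_names = names),
            class = "gene_set_collection")
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: term id, description, then member genes.
#'
#' @param path GMT file path.
#' @return A `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  desc <- vapply(parts, function(p) if (length(p) >= 2) p[[2]] else "", character(1))
  sets <- lapply(parts, function(p) if (length(p) >= 3) p[-(1:2)] else character(0))
  names(sets) <- ids
  gene_set_collection(sets, names = setNames(desc, ids))
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric p-value `P(X >= k)` for the overlap `k` between
#' the query gene list and each term, with Benjamini-Hochberg q-values across
#' terms. Term gene sets are intersected with the universe before testing.
#'
#' @param query Character vector of query genes (must be a subset of
#'   `universe`).
#' @param collection A `gene_set_collection`.
#' @param universe Character vector of background genes.
#' @return Data frame with columns `term_id`, `overlap_k`, `term_size_K`,
#'   `query_size_n`, `universe_N`, `p_hyper`, `q_bh`.
#' @export
ora_hypergeometric <- function(query, collection, universe) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  if (length(universe) == 0L || length(query) == 0L) {
    stop("query and universe must be non-empty", call. = FALSE)
  }
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    stop("query genes outside the universe: ",
         paste(head(outside, 5L), collapse = ", "), call. = FALSE)
  }
  N <- length(universe)
  n <- length(query)
  K <- vapply(collection$sets, function(s) length(intersect(s, universe)),
              integer(1))
  k <- vapply(collection$sets, function(s) length(intersect(s, query)),
              integer(1))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  data.frame(term_id = names(collection$sets),
             overlap_k = k, term_size_K = K,
             query_size_n = n, universe_N = N,
             p_hyper = p, q_bh = p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Jaccard similarity matrix between terms
#'
#' `J(A, B) = |A intersect B| / |A union B|`; the diagonal is 1.
#'
#' @param collection A `gene_set_collection` with at least two terms.
#' @return Symmetric numeric matrix in \[0, 1\].
#' @export
jaccard_matrix <- function(collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  sets <- collection$sets
  if (length(sets) < 2L) stop("need at least two terms", call. = FALSE)
  genes <- unique(unlist(sets, use.names = FALSE))
  inc <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  inc <- matrix(as.numeric(inc), nrow = length(genes),
                dimnames = list(genes, names(sets)))
  inter <- crossprod(inc)
  sizes <- colSums(inc)
  un <- outer(sizes, sizes, "+") - inter
  J <- inter / un
  diag(J) <- 1
  J
}

# Within-cluster dispersion: sum over clusters of the mean pairwise distance
# contribution sum_{i<j in cluster} d_ij / n_cluster.
dispersion_w <- function(d, cl) {
  w <- 0
  for (g in unique(cl)) {
    idx <- which(cl == g)
    if (length(idx) > 1L) {
      w <- w + sum(d[idx, idx]) / (2 * length(idx))
    }
  }
  w
}

#' Gap-statistic selection of the number of clusters
#'
#' For `k = 1..k_max`, terms are grouped by complete-linkage hierarchical
#' clustering on the supplied distance matrix and the log within-cluster
#' dispersion is compared to its mean over `n_boot` randomised reference
#' datasets: `Gap(k) = mean_b log W_k(ref_b) - log W_k(obs)`. The selected
#' `k` is the smallest with `Gap(k) >= Gap(k+1) - se(k+1)` (falling back to
#' `k_max` when none qualifies). Dispersions are floored at a tiny positive
#' value before taking logs so that perfectly tight clusters remain finite.
#'
#' @param distance Symmetric distance matrix with zero diagonal, entries in
#'   \[0, 1\].
#' @param k_max Largest number of clusters considered (default 15; capped at
#'   the number of terms with a warning).
#' @param n_boot Number of reference datasets (default 1000).
#' @param seed Integer seed.
#' @param ref_generator Function of no arguments returning a reference
#'   distance matrix of the same size. The default resamples the observed
#'   off-diagonal distances into a random symmetric matrix.
#' @return List with `k_opt` and `gap_curve` (data frame `k`, `gap`, `se`).
#' @export
gap_statistic_k <- function(distance, k_max = 15, n_boot = 1000, seed = NULL,
                            ref_generator = NULL) {
  stopifnot(is.matrix(distance), nrow(distance) == ncol(distance))
  if (any(abs(distance - t(distance)) > 1e-8) || any(diag(distance) > 1e-8)) {
    stop("distance must be symmetric with zero diagonal", call. = FALSE)
  }
  n <- nrow(distance)
  if (n == 1L) {
    warning("single term; k_opt = 1", call. = FALSE)
    return(list(k_opt = 1L,
                gap_curve = data.frame(k = 1L, gap = 0, se = 0)))
  }
  if (k_max >= n) {
    warning("k_max capped at the number of terms (", n, ")", call. = FALSE)
    k_max <- n
  }
  k_max <- assert_count(k_max, min = 1)
  with_local_seed(seed)
  eps <- 1e-12

  off <- distance[upper.tri(distance)]
  if (is.null(ref_generator)) {
    ref_generator <- function() {
      m <- matrix(0, n, n)
      m[upper.tri(m)] <- sample(off, length(off), replace = TRUE)
      m + t(m)
    }
  }

  log_w_curve <- function(d) {
    hc <- hclust(as.dist(d), method = "complete")
    vapply(seq_len(k_max), function(k) {
      log(max(dispersion_w(d, cutree(hc, k = k)), eps))
    }, numeric(1))
  }

  obs <- log_w_curve(distance)
  ref <- matrix(NA_real_, n_boot, k_max)
  for (b in seq_len(n_boot)) ref[b, ] <- log_w_curve(ref_generator())
  gap <- colMeans(ref) - obs
  se <- apply(ref, 2, sd) * sqrt(1 + 1 / n_boot)

  k_opt <- k_max
  for (k in seq_len(k_max - 1L)) {
    if (gap[k] >= gap[k + 1L] - se[k + 1L]) { k_opt <- k; break }
  }
  list(k_opt = as.integer(k_opt),
       gap_curve = data.frame(k = seq_len(k_max), gap = gap, se = se))
}

#' Cluster enriched terms by gene-membership similarity
#'
#' Complete-linkage hierarchical clustering of terms on the distance
#' `1 - Jaccard`, with the number of clusters selected by the gap statistic.
#' Reference datasets draw random gene sets from the collection's gene
#' universe preserving each term's set size, which keeps the null comparable
#' to the observed collection.
#'
#' @param collection A `gene_set_collection` (>= 2 terms).
#' @param k_max,n_boot,seed Passed to [gap_statistic_k()].
#' @return List of class `term_clusters` with `k_opt`, `assignments` (named
#'   integer vector), `gap_curve` and `jaccard`.
#' @export
cluster_terms <- function(collection, k_max = 15, n_boot = 1000, seed = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  J <- jaccard_matrix(collection)
  d <- 1 - J
  diag(d) <- 0
  universe <- unique(unlist(collection$sets, use.names = FALSE))
  sizes <- lengths(collection$sets)
  ref_gen <- function() {
    sets <- lapply(sizes, function(s) sample(universe, min(s, length(universe))))
    names(sets) <- names(collection$sets)
    dd <- 1 - jaccard_matrix(gene_set_collection(sets))
    diag(dd) <- 0
    dd
  }
  gs <- gap_statistic_k(d, k_max = k_max, n_boot = n_boot, seed = seed,
                        ref_generator = ref_gen)
  hc <- hclust(as.dist(d), method = "complete")
  assignments <- cutree(hc, k = gs$k_opt)
  structure(list(k_opt = gs$k_opt, assignments = assignments,
                 gap_curve = gs$gap_curve, jaccard = J),
            class = "term_clusters")
}
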