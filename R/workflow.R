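# Dataset preprocessing used ahead of enrichment: fraction-of-total
# normalization, half-minimum imputation, per-lipid z-scoring, complete-
# linkage hierarchical clustering, and the per-cluster enrichment workflow.

#' Read a lipid abundance matrix from CSV/TSV
#'
#' Expects a header row, lipid names in the first column, one column per
#' sample, nonnegative numeric intensities; empty cells are missing values.
#'
#' @param path Input file path.
#' @param tsv Use tab as delimiter (default comma).
#' @return Numeric matrix with lipid rownames and sample colnames.
#' @export
read_abundance_matrix <- function(path, tsv = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = if (tsv) "\t" else ",",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Fraction-of-total normalization
#'
#' Expresses every lipid as a ratio of the summed intensity of its sample,
#' so each column sums to 1. Missing entries stay missing and are excluded
#' from the sums. Idempotent.
#'
#' @param matrix Numeric lipid-by-sample matrix.
#' @return Normalized matrix of the same shape.
#' @export
normalize_fraction_of_total <- function(matrix) {
  sums <- colSums(matrix, na.rm = TRUE)
  n_obs <- colSums(!is.na(matrix))
  if (any(n_obs == 0L))
    stop("all-missing sample column(s): ",
         paste(colnames(matrix)[n_obs == 0L], collapse = ", "))
  if (any(sums <= 0))
    stop("non-positive column sum(s): ",
         paste(colnames(matrix)[sums <= 0], collapse = ", "))
  sweep(matrix, 2L, sums, "/")
}

#' Half-minimum imputation
#'
#' Replaces every missing cell with half of the minimum positive value of
#' the original matrix (a global constant, computed before replacement). In
#' the standard pipeline imputation precedes normalization.
#'
#' @param matrix Numeric lipid-by-sample matrix.
#' @return Matrix with no missing values.
#' @export
impute_half_minimum <- function(matrix) {
  pos <- matrix[!is.na(matrix) & matrix > 0]
  if (!length(pos)) stop("no positive values to derive the half-minimum from")
  matrix[is.na(matrix)] <- min(pos) / 2
  matrix
}

#' Per-lipid z-scoring
#'
#' Scales every row to mean 0 and standard deviation 1. Constant rows cannot
#' be scaled; they are dropped with a warning.
#'
#' @param matrix Numeric lipid-by-sample matrix without missing values.
#' @return Matrix of z-scores (possibly fewer rows).
#' @export
zscore_rows <- function(matrix) {
  mu <- rowMeans(matrix)
  sd <- apply(matrix, 1L, stats::sd)
  constant <- sd == 0 | is.na(sd)
  if (any(constant)) {
    warning(sum(constant), " constant row(s) excluded from z-scoring: ",
            paste(utils::head(rownames(matrix)[constant], 5), collapse = ", "))
    matrix <- matrix[!constant, , drop = FALSE]
    mu <- mu[!constant]; sd <- sd[!constant]
  }
  (matrix - mu) / sd
}

#' Complete-linkage hierarchical clustering of lipids
#'
#' Agglomerative clustering of the rows on Euclidean distances with complete
#' linkage, cut into exactly `k` clusters. Deterministic given the input row
#' order (ties in merge heights are resolved by `stats::hclust`'s fixed
#' agglomeration order).
#'
#' @param matrix Numeric lipid-by-sample matrix (rows are clustered).
#' @param k Number of clusters, `1 <= k <= nrow(matrix)`.
#' @return A `cluster_assignment`: `cluster` (named integer vector in
#'   1..k), `tree` (the `hclust` object), `k`.
#' @export
hierarchical_clusters <- function(matrix, k) {
  n <- nrow(matrix)
  if (k < 1L || k > n) stop("k must satisfy 1 <= k <= number of lipids")
  tree <- stats::hclust(stats::dist(matrix, method = "euclidean"),
                        method = "complete")
  cl <- stats::cutree(tree, k = k)
  structure(list(cluster = cl, tree = tree, k = k),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d lipids in %d clusters (sizes: %s)\n",
              length(x$cluster), x$k,
              paste(tabulate(x$cluster, x$k), collapse = ", ")))
  invisible(x)
}

#' Cluster-then-enrich workflow
#'
#' The preprocessing and per-cluster enrichment pipeline: half-minimum
#' imputation, fraction-of-total normalization, per-lipid z-scoring (used
#' only for clustering), complete-linkage clustering into `k` groups, then
#' one target-list Fisher enrichment per cluster with that cluster as target
#' and all matched lipids as the shared universe.
#'
#' @param matrix Numeric lipid-by-sample abundance matrix; rownames are raw
#'   lipid names.
#' @param k Number of clusters.
#' @param ontology A `lion_ontology`.
#' @param term_subset,prune_redundant,min_term_size,alpha Passed to
#'   [fisher_enrichment()].
#' @param synonyms Class-alias table for name matching.
#' @return A list: `reports` (one enrichment report per cluster),
#'   `clusters` (`cluster_assignment` over canonical names), `match`
#'   (match report), `processed` (the normalized matrix on matched lipids).
#' @export
cluster_enrichment_workflow <- function(matrix, k, ontology,
                                        term_subset = NULL,
                                        prune_redundant = FALSE,
                                        min_term_size = 1L, alpha = 0.05,
                                        synonyms = default_synonyms()) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)))
  mm <- match_names(rownames(matrix), ontology, synonyms)
  keep <- mm$mapping$matched
  if (!any(keep)) stop("no input lipids matched the ontology")
  m <- matrix[keep, , drop = FALSE]
  canon <- mm$mapping$canonical_name[keep]
  if (anyDuplicated(canon)) {
    # duplicates after canonicalization map to the same node: collapse by sum
    warning("duplicate lipids after canonicalization collapsed by summation")
    m <- rowsum(m, group = canon, na.rm = FALSE)
    canon <- rownames(m)
  } else {
    rownames(m) <- canon
  }
  m <- impute_half_minimum(m)
  m <- normalize_fraction_of_total(m)
  z <- zscore_rows(m)
  cl <- hierarchical_clusters(z, k)
  universe <- rownames(z)
  reports <- lapply(seq_len(k), function(g) {
    members <- names(cl$cluster)[cl$cluster == g]
    fisher_enrichment(members, universe, ontology, term_subset,
                      prune_redundant, min_term_size, alpha)
  })
  names(reports) <- paste0("cluster_", seq_len(k))
  list(reports = reports, clusters = cl,
       match = mm$report, processed = m)
}

#' Write a cluster assignment as CSV
#' @param clusters A `cluster_assignment`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_assignment <- function(clusters, path) {
  utils::write.csv(data.frame(lipid = names(clusters$cluster),
                              cluster = unname(clusters$cluster)),
                   path, row.names = FALSE)
  invisible(path)
}
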