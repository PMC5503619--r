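# Hierarchical clustering support: Pearson/Euclidean distances, agglomerative
# trees (complete / average / Ward), tree cutting and cophenetic distances.

#' Distance matrix between samples or genes
#'
#' Pearson distance is `1 - r` (range 0..2); Euclidean is the usual L2
#' distance. Vectors that are constant under the Pearson metric have no
#' defined correlation and raise an error naming the offending item.
#'
#' @param m an [expr_matrix()].
#' @param metric `"pearson"` or `"euclidean"`.
#' @param axis cluster `"samples"` (columns) or `"genes"` (rows).
#' @return Symmetric nonnegative matrix with zero diagonal.
#' @export
distance_matrix <- function(m, metric = c("pearson", "euclidean"),
                            axis = c("samples", "genes")) {
  metric <- match.arg(metric)
  axis <- match.arg(axis)
  x <- expr_values(m)
  if (axis == "genes") x <- t(x)           # items become columns
  if (ncol(x) < 2) stop("need >= 2 items to compute distances")
  if (metric == "pearson") {
    sds <- matrixStats::colSds(x)
    if (any(sds == 0))
      stop("constant vector(s) under pearson metric: ",
           paste(utils::head(colnames(x)[sds == 0], 5), collapse = ", "))
    d <- 1 - stats::cor(x)
  } else {
    d <- as.matrix(stats::dist(t(x), method = "euclidean"))
  }
  d[d < 0] <- 0                            # clip fp noise
  diag(d) <- 0
  (d + t(d)) / 2
}

#' Agglomerative hierarchical clustering
#'
#' Standard agglomerative clustering of a distance matrix; `linkage =
#' "ward"` (Ward's minimum-variance criterion, intended for Euclidean
#' distances) maps to the Ward.D2 merge rule.
#'
#' @param d symmetric distance matrix (or `dist`).
#' @param linkage `"complete"`, `"average"` or `"ward"`.
#' @return An `hclust` tree (merge history, heights, leaf labels).
#' @export
hierarchical_cluster <- function(d, linkage = c("complete", "average", "ward")) {
  linkage <- match.arg(linkage)
  if (is.matrix(d)) {
    if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
      stop("distance matrix must be symmetric")
    d <- stats::as.dist(d)
  }
  if (!inherits(d, "dist")) stop("d must be a distance matrix or dist object")
  method <- switch(linkage, complete = "complete", average = "average",
                   ward = "ward.D2")
  stats::hclust(d, method = method)
}

#' Cut a dendrogram into k clusters
#'
#' Removes the `k - 1` highest merges; clusters are numbered by first
#' appearance in the leaf ordering of the input data.
#'
#' @param dend an `hclust` tree.
#' @param k number of clusters, `1 <= k <= n`.
#' @return Integer labels named by leaf id.
#' @export
cut_tree <- function(dend, k) {
  n <- length(dend$order)
  if (k < 1 || k > n) stop("k must lie in [1, ", n, "]")
  stats::cutree(dend, k = k)
}

#' Cophenetic distance matrix of a dendrogram
#'
#' Entry (i, j) is the height of the lowest merge containing both leaves;
#' for the linkages used here the result is ultrametric.
#'
#' @param dend an `hclust` tree.
#' @return Symmetric matrix of cophenetic distances with zero diagonal.
#' @export
cophenetic_distances <- function(dend) {
  as.matrix(stats::cophenetic(dend))
}
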