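#' Pearson correlation distance matrix
#'
#' `d(i, j) = 1 - r(i, j)` between samples (columns) or peaks (rows) of a
#' `CountMatrix`. Constant vectors have no defined correlation and are
#' rejected; filter them out first.
#'
#' @param m A `CountMatrix` (any stage).
#' @param axis `"samples"` (columns) or `"peaks"` (rows).
#' @return Symmetric distance matrix with zero diagonal and dimnames.
#' @export
correlation_distance <- function(m, axis = c("samples", "peaks")) {
  stopifnot(inherits(m, "CountMatrix"))
  axis <- match.arg(axis)
  X <- if (axis == "samples") m$values else t(m$values)
  if (ncol(X) < 2L) stop("need at least 2 ", axis, " to compute distances")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant ", sub("s$", "", axis), ": ",
         colnames(X)[which(sds == 0)[1L]])
  d <- 1 - stats::cor(X)
  diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Unweighted average linkage on a precomputed distance matrix: the distance
#' between two clusters is the mean of all cross-pair distances.
#'
#' @param d Symmetric numeric distance matrix with zero diagonal.
#' @param labels Leaf labels (default: `rownames(d)`).
#' @return A `Dendrogram`: list with `merge` (hclust-style merge matrix),
#'   `height`, `labels` and the underlying `hclust` object.
#' @export
average_linkage <- function(d, labels = rownames(d)) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-12,
                                              check.attributes = FALSE)))
    stop("distance matrix must be symmetric")
  if (is.null(labels)) labels <- paste0("leaf_", seq_len(nrow(d)))
  dd <- stats::as.dist(d)
  h <- stats::hclust(dd, method = "average")
  h$labels <- labels
  if (is.unsorted(h$height))
    warning("non-monotone merge heights in average-linkage tree",
            call. = FALSE)
  structure(list(merge = h$merge, height = h$height, labels = labels,
                 hclust = h),
            class = "Dendrogram")
}

#' @export
print.Dendrogram <- function(x, ...) {
  cat("Dendrogram with", length(x$labels), "leaves;",
      length(x$height), "merges, max height", format(max(x$height)), "\n")
  invisible(x)
}

#' Cut a dendrogram into k clusters
#'
#' Cluster labels are deterministic: clusters are numbered by first
#' appearance in leaf (observation) order, as in [stats::cutree()].
#'
#' @param dend A `Dendrogram`.
#' @param k Number of clusters, `1 <= k <=` number of leaves.
#' @return Named integer vector of cluster assignments.
#' @export
cut_tree <- function(dend, k) {
  stopifnot(inherits(dend, "Dendrogram"))
  n <- length(dend$labels)
  if (k < 1L || k > n) stop("k must be between 1 and the number of leaves")
  stats::cutree(dend$hclust, k = k)
}

#' Export a dendrogram as a Newick string
#'
#' @param dend A `Dendrogram`.
#' @return Newick-format character scalar (requires the `ape` package).
#' @export
as_newick <- function(dend) {
  stopifnot(inherits(dend, "Dendrogram"))
  if (!requireNamespace("ape", quietly = TRUE))
    stop("the 'ape' package is required for Newick export")
  ape::write.tree(ape::as.phylo(dend$hclust))
}

#' Cluster the samples (or peaks) of a CountMatrix
#'
#' Convenience wrapper chaining [correlation_distance()] and
#' [average_linkage()]. For peak-axis clustering the matrix is first
#' row-normalized with [relative_intensity()] (heatmap-style display
#' transformation) when it is at the `normalized` stage.
#'
#' @param m A `CountMatrix`.
#' @param axis `"samples"` or `"peaks"`.
#' @return A `Dendrogram`.
#' @export
cluster_matrix <- function(m, axis = c("samples", "peaks")) {
  axis <- match.arg(axis)
  if (axis == "peaks" && m$stage == "normalized")
    m <- relative_intensity(m)
  d <- correlation_distance(m, axis = axis)
  average_linkage(d)
}
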