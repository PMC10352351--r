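## grouping module: group cells sharing biological signal within each batch,
## either by SNN-graph Louvain clustering or by user-supplied cell-type
## labels. Group labels are namespaced "<batch>::<group>".

## Internal: k nearest neighbours (excluding self) by Euclidean distance.
knn_indices <- function(x, k) {
  n <- nrow(x)
  k <- min(k, n - 1)
  if (k < 1) return(matrix(integer(0), nrow = n, ncol = 0))
  nn <- RANN::nn2(x, k = k + 1)$nn.idx
  ## drop the self column (usually first, but guard against exact ties)
  out <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    row <- nn[i, ]
    row <- row[row != i]
    out[i, ] <- row[seq_len(k)]
  }
  out
}

## Internal: shared-nearest-neighbour graph with Jaccard weights on the kNN
## sets; edges of weight 0 are dropped.
snn_graph <- function(x, n_neighbors) {
  n <- nrow(x)
  if (n == 1) return(igraph::make_empty_graph(1, directed = FALSE))
  k <- min(n_neighbors, n - 1)
  nn <- knn_indices(x, k)
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), each = ncol(nn)),
                              j = as.vector(t(nn)), x = 1, dims = c(n, n))
  shared <- adj %*% Matrix::t(adj)          # |kNN(i) inter kNN(j)|
  shared <- methods::as(shared, "TsparseMatrix")
  keep <- shared@i < shared@j & shared@x > 0
  i <- shared@i[keep] + 1L
  j <- shared@j[keep] + 1L
  w <- shared@x[keep] / (2 * k - shared@x[keep])   # Jaccard: |A^B|/|AuB|
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(i))
    g <- igraph::add_edges(g, rbind(i, j), weight = w)
  g
}

## Internal: Louvain clustering of a feature matrix; returns integer labels.
louvain_cluster <- function(x, n_neighbors, seed, resolution = 1) {
  if (nrow(x) == 1) return(1L)
  g <- snn_graph(x, n_neighbors)
  if (igraph::ecount(g) == 0) return(seq_len(nrow(x)))
  cl <- with_seed(seed, igraph::cluster_louvain(g, resolution = resolution))
  as.integer(igraph::membership(cl))
}

#' Cluster cells within each batch
#'
#' Per batch independently: k nearest neighbours by Euclidean distance on the
#' HVG-restricted log-scale expression, a shared-nearest-neighbour graph with
#' Jaccard edge weights, then Louvain modularity clustering. The number of
#' clusters is not prespecified. Labels are namespaced by batch, so clusters
#' never span batches.
#'
#' @param data an [expression_data] on the log scale.
#' @param hvg character vector of gene IDs to cluster on (see [select_hvg()]).
#' @param n_neighbors number of neighbours for the kNN graph (default 10),
#'   clamped to batch size minus one.
#' @param seed integer seed (Louvain is stochastic).
#' @param resolution Louvain resolution parameter.
#' @return A `cell_grouping` object: per-cell `labels`
#'   (`"<batch>::<cluster>"`) and `source = "clustering"`.
#' @export
cluster_within_batch <- function(data, hvg, n_neighbors = 10, seed = 1,
                                 resolution = 1) {
  stopifnot(inherits(data, "expr_data"), length(hvg) >= 1)
  gi <- match(hvg, data$gene_ids)
  if (anyNA(gi)) fr_stop("hvg contains unknown gene IDs")
  labels <- character(nrow(data$values))
  for (b in unique(data$metadata$batch)) {
    idx <- which(data$metadata$batch == b)
    if (!length(idx)) fr_stop("batch '%s' is empty", b)
    x <- as_dense(data$values[idx, gi, drop = FALSE])
    memb <- louvain_cluster(x, n_neighbors, stage_seed(seed, "cluster", b),
                            resolution = resolution)
    labels[idx] <- paste0(b, "::", memb)
  }
  structure(list(labels = labels, source = "clustering"),
            class = "cell_grouping")
}

#' Adopt user-supplied cell-type labels as the grouping
#'
#' Reference-based grouping: labels from a supervised annotation (e.g. a
#' cell-type classifier run beforehand) are namespaced by batch and used in
#' place of clustering. Cell types absent from a batch simply yield no group.
#'
#' @param data an [expression_data] whose metadata has the label column.
#' @param celltype_column metadata column to use (default `"cell_type"`).
#' @return A `cell_grouping` with `source = "provided"`.
#' @export
adopt_labels <- function(data, celltype_column = "cell_type") {
  stopifnot(inherits(data, "expr_data"))
  if (!celltype_column %in% names(data$metadata))
    fr_stop("metadata has no column '%s'", celltype_column)
  ct <- data$metadata[[celltype_column]]
  n_missing <- sum(is.na(ct) | ct == "")
  if (n_missing > 0)
    fr_stop("%d cell(s) have missing '%s' labels", n_missing, celltype_column)
  labels <- paste0(data$metadata$batch, "::", ct)
  structure(list(labels = labels, source = "provided"), class = "cell_grouping")
}

#' @export
print.cell_grouping <- function(x, ...) {
  cat(sprintf("cell_grouping (%s): %d cells, %d groups\n",
              x$source, length(x$labels), length(unique(x$labels))))
  invisible(x)
}
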