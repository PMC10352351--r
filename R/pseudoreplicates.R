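## pseudoreplicates module: mutual-nearest-cluster (MNC) graph across batches
## and the replicate matrix M its connected components define.

#' Build the mutual-nearest-cluster graph
#'
#' Nodes are the (batch, condition, group) cells of a pseudo-bulk set, with
#' centroids equal to the mean of their pseudo-bulk rows (optionally
#' restricted to a feature subset such as the HVGs, on the standardized
#' scale). For every pair of distinct batches, node `u` is linked to its
#' nearest node `v` in the other batch (1 - Pearson correlation of centroids
#' by default) iff `u` is in turn `v`'s nearest node in `u`'s batch. In
#' condition-aware mode only nodes of the same condition may be linked, so
#' biological differences between conditions are never treated as unwanted
#' variation. Ties are broken by node ID order.
#'
#' @param pb a `pseudobulk_set` (see [construct_pseudobulk()]).
#' @param features optional integer or logical index of columns to use for
#'   centroids (e.g. HVG positions).
#' @param per_condition restrict edges to same-condition node pairs.
#' @param metric `"pearson"` (1 - correlation) or `"euclidean"`.
#' @return An `mnc_graph`: `nodes` (data.frame `node_id`, `batch`, `group`,
#'   `condition`), `centroids` (nodes x features), `edges` (data.frame
#'   `from`, `to`, `condition`).
#' @export
build_mnc_graph <- function(pb, features = NULL, per_condition = TRUE,
                            metric = c("pearson", "euclidean")) {
  metric <- match.arg(metric)
  stopifnot(inherits(pb, "pseudobulk_set"))
  node_ids <- unique(pb$rows$node_id)           # already in sorted order
  nodes <- pb$rows[!duplicated(pb$rows$node_id),
                   c("node_id", "batch", "group", "condition")]
  rownames(nodes) <- NULL
  vals <- pb$values
  if (!is.null(features)) vals <- vals[, features, drop = FALSE]
  cent <- rowsum(vals, pb$rows$node_id)          # sorted by node_id
  cent <- cent / as.vector(table(pb$rows$node_id))
  cent <- cent[match(nodes$node_id, rownames(cent)), , drop = FALSE]

  if (length(unique(nodes$batch)) < 2) {
    warning("fewer than 2 batches in scope; MNC graph has no edges",
            call. = FALSE)
    return(structure(list(nodes = nodes, centroids = cent,
                          edges = data.frame(from = character(0),
                                             to = character(0),
                                             condition = character(0))),
                     class = "mnc_graph"))
  }

  node_dist <- function(i, j) {
    a <- cent[i, ]; b <- cent[j, ]
    if (metric == "euclidean") return(sqrt(sum((a - b)^2)))
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(2)  # worst case
    1 - stats::cor(a, b)
  }
  nearest_in <- function(i, cand) {
    if (!length(cand)) return(NA_integer_)
    d <- vapply(cand, function(j) node_dist(i, j), numeric(1))
    cand[which.min(d)]                           # first minimum: ID order
  }

  scopes <- if (per_condition) split(seq_len(nrow(nodes)), nodes$condition)
            else list(all = seq_len(nrow(nodes)))
  edges <- list()
  for (sc in scopes) {
    bs <- unique(nodes$batch[sc])
    if (length(bs) < 2) next                     # single-batch condition
    for (bi in seq_along(bs)) for (bj in seq_along(bs)) {
      if (bi >= bj) next
      ui <- sc[nodes$batch[sc] == bs[bi]]
      uj <- sc[nodes$batch[sc] == bs[bj]]
      for (u in ui) {
        v <- nearest_in(u, uj)
        if (is.na(v)) next
        if (identical(nearest_in(v, ui), u)) {
          edges[[length(edges) + 1L]] <-
            data.frame(from = nodes$node_id[u], to = nodes$node_id[v],
                       condition = nodes$condition[u],
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(from = character(0), to = character(0),
                           condition = character(0))
  structure(list(nodes = nodes, centroids = cent, edges = edges),
            class = "mnc_graph")
}

#' @export
print.mnc_graph <- function(x, ...) {
  cat(sprintf("mnc_graph: %d nodes, %d mutual-nearest edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Replicate sets from the MNC graph components
#'
#' Connected components of the MNC graph define the pseudo-replicate sets:
#' every pseudo-bulk row of every node in a component joins that component's
#' set. Singleton nodes become singleton sets; their rows contribute zero
#' residual, so batch-unique populations are left untouched during factor
#' estimation.
#'
#' @param graph an `mnc_graph`.
#' @param pb the `pseudobulk_set` the graph was built from.
#' @return A `replicate_matrix`: integer `sets` (one set ID per pseudo-bulk
#'   row), `n_sets`, and the component membership per node. Use
#'   [as.matrix()] for the explicit binary C_b x N_b matrix M.
#' @export
replicate_sets_from_graph <- function(graph, pb) {
  stopifnot(inherits(graph, "mnc_graph"), inherits(pb, "pseudobulk_set"))
  ids <- graph$nodes$node_id
  if (!all(pb$rows$node_id %in% ids))
    fr_stop("graph nodes do not cover all pseudo-bulk provenance cells")
  g <- igraph::graph_from_data_frame(graph$edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership[ids]
  sets <- as.integer(comp[match(pb$rows$node_id, ids)])
  sets <- match(sets, sort(unique(sets)))        # compact 1..N_b
  structure(list(sets = sets, n_sets = length(unique(sets)),
                 node_component = stats::setNames(as.integer(comp), ids)),
            class = "replicate_matrix")
}

#' Build a replicate matrix directly from set labels
#'
#' @param sets vector assigning each observation to one replicate set.
#' @export
replicate_matrix <- function(sets) {
  f <- factor(sets)
  structure(list(sets = as.integer(f), n_sets = nlevels(f),
                 node_component = NULL),
            class = "replicate_matrix")
}

#' @export
as.matrix.replicate_matrix <- function(x, ...) {
  M <- matrix(0, length(x$sets), x$n_sets)
  M[cbind(seq_along(x$sets), x$sets)] <- 1
  M
}

#' @export
print.replicate_matrix <- function(x, ...) {
  cat(sprintf("replicate_matrix: %d observations in %d sets (%d singleton)\n",
              length(x$sets), x$n_sets, sum(tabulate(x$sets) == 1)))
  invisible(x)
}

#' Export replicate-set assignments as TSV (for audit)
#'
#' @param M a `replicate_matrix`.
#' @param pb the matching `pseudobulk_set`.
#' @param path output TSV path.
#' @export
write_replicates <- function(M, pb, path) {
  df <- cbind(pb$rows, replicate_set = M$sets)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(NULL)
}
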