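## pseudobulk module: build the pseudo-bulk sketch Z_b of the full matrix
## within each (batch, condition, group) cell. Groups with fewer than k cells
## are carried through as single-cell rows.

#' Construct pseudo-bulk profiles
#'
#' Within each (batch, condition, group) cell with at least `k` cells, cells
#' are split into `k` near-equal subsets (sizes differ by at most one) and
#' each subset is collapsed to one pseudo-bulk row:
#' * `mean_random_split` — gene-wise mean of a random (seeded) split; works on
#'   any scale.
#' * `pool_divide_random` — gene-wise sum of a random split; counts only.
#' * `pool_divide_libsize` — gene-wise sum with cells ordered by library size
#'   and dealt round-robin to subsets, so each subset spans the library-size
#'   range; counts only.
#' Groups with fewer than `k` cells contribute one row per cell. The optional
#' negative-binomial resampling of pooled counts (`nb_dispersion`) redraws
#' each pooled sum from NB(mean = sum, size = dispersion); it is off by
#' default.
#'
#' @param values cells x genes matrix (the scale the sketch should live on).
#' @param grouping a `cell_grouping` (see [cluster_within_batch()],
#'   [adopt_labels()]).
#' @param metadata per-cell data.frame with `batch` and `condition` columns.
#' @param k target number of pseudo-bulk per group (default 30).
#' @param strategy one of `"mean_random_split"`, `"pool_divide_libsize"`,
#'   `"pool_divide_random"`.
#' @param seed integer seed for the random splits.
#' @param counts logical: `values` are raw counts (required for the
#'   pool-divide strategies).
#' @param nb_dispersion optional NB size parameter for post-hoc resampling of
#'   pooled sums (pool-divide strategies only).
#' @return A `pseudobulk_set`: `values` (C_b x G), `rows` (data.frame with
#'   `batch`, `group`, `condition`, `node_id`, `size`), `members` (list of
#'   member cell indices), `strategy`.
#' @export
construct_pseudobulk <- function(values, grouping, metadata, k = 30,
                                 strategy = c("mean_random_split",
                                              "pool_divide_libsize",
                                              "pool_divide_random"),
                                 seed = 1, counts = FALSE,
                                 nb_dispersion = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(grouping, "cell_grouping"), k >= 1)
  values <- as_dense(values)
  pooled <- strategy != "mean_random_split"
  if (pooled && !counts)
    fr_stop("strategy '%s' requires count-scale data", strategy)
  cell_of <- paste0(grouping$labels, "@", metadata$condition)
  cells_by_node <- split(seq_len(nrow(values)), cell_of)
  ## deterministic node order
  cells_by_node <- cells_by_node[order(names(cells_by_node))]
  val_list <- list()
  member_list <- list()
  prov <- list()
  for (node in names(cells_by_node)) {
    idx <- cells_by_node[[node]]
    n <- length(idx)
    grp <- sub("@[^@]*$", "", node)
    cond <- sub("^.*@", "", node)
    batch <- sub("::.*$", "", grp)
    if (n < k) {
      subsets <- as.list(idx)
    } else {
      if (strategy == "pool_divide_libsize") {
        ord <- idx[order(rowSums(values[idx, , drop = FALSE]),
                         idx)]                      # deterministic
        subsets <- split(ord, rep_len(seq_len(k), n))
      } else {
        perm <- with_seed(stage_seed(seed, "pseudobulk", node),
                          sample(idx))
        subsets <- split(perm, rep_len(seq_len(k), n))
      }
    }
    agg <- vapply(subsets, function(s) {
      m <- values[s, , drop = FALSE]
      if (pooled) colSums(m) else colMeans(m)
    }, numeric(ncol(values)))
    agg <- t(agg)
    if (pooled && !is.null(nb_dispersion)) {
      agg[] <- with_seed(stage_seed(seed, "pseudobulk-nb", node),
                         stats::rnbinom(length(agg), mu = as.vector(agg),
                                        size = nb_dispersion))
    }
    val_list[[node]] <- agg
    member_list <- c(member_list, unname(subsets))
    prov[[node]] <- data.frame(batch = batch, group = grp, condition = cond,
                               node_id = node, size = lengths(subsets),
                               stringsAsFactors = FALSE)
  }
  out_values <- do.call(rbind, val_list)
  rownames(out_values) <- NULL
  rows <- do.call(rbind, prov)
  rownames(rows) <- NULL
  structure(list(values = out_values, rows = rows, members = member_list,
                 strategy = strategy),
            class = "pseudobulk_set")
}

#' @export
print.pseudobulk_set <- function(x, ...) {
  cat(sprintf("pseudobulk_set (%s): %d pseudo-bulk x %d genes, %d nodes\n",
              x$strategy, nrow(x$values), ncol(x$values),
              length(unique(x$rows$node_id))))
  invisible(x)
}
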