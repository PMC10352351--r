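## The user-facing fitting function and its S3 methods. A flat run is the
## special case of a one-level, one-collection merge tree.

#' Pipeline parameters
#'
#' Collects the tunable parameters of the integration pipeline with the
#' field-standard defaults: `k_ruv = 20` unwanted factors (use 10 for
#' ADT/CyTOF panels, where `hvg_n = NULL` should also be set so all features
#' are used), `k_pseudobulk = 30` pseudo-bulk per group, 10 neighbours in the
#' SNN graph, top 2000 HVGs.
#'
#' @param k_ruv number of unwanted factors to remove.
#' @param k_pseudobulk pseudo-bulk per (batch, condition, group) cell.
#' @param n_neighbors SNN graph neighbours for within-batch clustering.
#' @param hvg_n number of highly variable genes (NULL = use all features).
#' @param strategy pseudo-bulk strategy (see [construct_pseudobulk()]).
#' @param per_condition build the mutual-nearest-cluster graph within each
#'   condition (recommended whenever a condition column exists).
#' @param grouping NULL for clustering, a metadata column name for
#'   reference-based grouping, or a precomputed `cell_grouping`.
#' @param resolution Louvain resolution.
#' @param mnc_metric centroid distance: `"pearson"` (1 - correlation) or
#'   `"euclidean"`.
#' @param seg_quantile fraction of genes kept by the stability-score fallback
#'   when no SEG list is supplied.
#' @param cosine apply cosine normalization during preprocessing.
#' @param base log base of the normalization.
#' @param nb_dispersion optional NB size for pooled-count resampling
#'   (pool-divide strategies; off by default).
#' @export
fastruv_params <- function(k_ruv = 20, k_pseudobulk = 30, n_neighbors = 10,
                           hvg_n = 2000,
                           strategy = c("mean_random_split",
                                        "pool_divide_libsize",
                                        "pool_divide_random"),
                           per_condition = TRUE, grouping = NULL,
                           resolution = 1, mnc_metric = c("pearson", "euclidean"),
                           seg_quantile = 0.2, cosine = TRUE, base = 2,
                           nb_dispersion = NULL) {
  list(k_ruv = k_ruv, k_pseudobulk = k_pseudobulk, n_neighbors = n_neighbors,
       hvg_n = hvg_n, strategy = match.arg(strategy),
       per_condition = per_condition, grouping = grouping,
       resolution = resolution, mnc_metric = match.arg(mnc_metric),
       seg_quantile = seg_quantile, cosine = cosine, base = base,
       nb_dispersion = nb_dispersion)
}

#' Remove multi-level unwanted variation from single-cell data
#'
#' Fits the pseudo-bulk factor model and returns the fully adjusted
#' expression matrix. Cells are grouped within each batch (graph clustering
#' or supplied labels), pseudo-bulk profiles summarize each (batch,
#' condition, group) cell, mutual-nearest-cluster components across batches
#' define pseudo-replicates, the unwanted-variation loadings are the top
#' right singular vectors of the replicate-residual pseudo-bulk matrix, the
#' per-cell factors are regressed from stably expressed genes, and the
#' unwanted component is subtracted. With a merge `tree` the procedure runs
#' level by level (e.g. cohorts within studies first, then across studies),
#' each level consuming the previous level's adjusted matrix.
#'
#' Counts are size-factor log-normalized and (by default) cosine-normalized
#' once up front; adjusted output is returned on that log scale by inverting
#' the gene-wise standardization only.
#'
#' @param data an [expression_data] (counts or log scale).
#' @param tree optional [merge_tree()]; the default is a single level with
#'   one collection holding every batch.
#' @param seg optional character vector of stably-expressed (negative
#'   control) gene IDs; when absent a heuristic stability score picks the top
#'   [fastruv_params()]`$seg_quantile` fraction.
#' @param seed integer seed driving every stochastic stage through
#'   independent substreams.
#' @param params a [fastruv_params()] list.
#' @param ... convenience overrides of individual `params` entries, e.g.
#'   `k_ruv = 10`.
#' @return An object of class `fastruv`: `adjusted` (an [expression_data] on
#'   the log scale), `models` (fitted `ruv_model` per collection),
#'   `diagnostics` (per-collection table), `tree`, `params`, `seed`, `call`.
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 60, cells_per_sample = 30,
#'                                   n_samples_per_condition = 2, seed = 7))
#' fit <- fastruv(sim$data, seed = 7, k_ruv = 2, k_pseudobulk = 5)
#' fit
#' @export
fastruv <- function(data, tree = NULL, seg = NULL, seed = 1,
                    params = fastruv_params(), ...) {
  stopifnot(inherits(data, "expr_data"))
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(params))
    if (length(bad)) fr_stop("unknown parameter(s): %s", paste(bad, collapse = ", "))
    params[names(dots)] <- dots
  }
  counts <- NULL
  if (params$strategy != "mean_random_split") {
    if (data$scale != "counts")
      fr_stop("pool-divide pseudo-bulk requires count-scale input")
    counts <- as_dense(data$values)
  }
  ln <- if (data$scale == "counts") lognormalize(data, base = params$base) else data
  vals <- as_dense(ln$values)
  if (params$cosine) {
    vals <- cosine_normalize(vals)
    attr(vals, "cell_norms") <- NULL
  }
  work <- expression_data(vals, ln$metadata, gene_ids = ln$gene_ids,
                          cell_ids = ln$cell_ids, scale = "lognorm")
  if (is.null(tree)) {
    tree <- merge_tree(list(merge_collection(
      members = unique(work$metadata$batch), name = "all",
      batch_column = "batch")))
  }
  res <- run_tree(work, tree, seg = seg, seed = seed, params = params,
                  counts = counts)
  structure(list(adjusted = res$data, models = res$models,
                 diagnostics = res$diagnostics, tree = tree, params = params,
                 seed = seed, call = match.call()),
            class = "fastruv")
}

#' @export
print.fastruv <- function(x, ...) {
  cat("fastruv fit\n")
  cat(sprintf("  %d cells x %d genes, %d level(s), %d fitted collection(s)\n",
              nrow(x$adjusted$values), ncol(x$adjusted$values),
              length(x$tree$levels), length(x$models)))
  if (!is.null(x$diagnostics)) {
    d <- x$diagnostics
    for (i in seq_len(nrow(d)))
      cat(sprintf("  level %d | %-12s %6d cells, %s\n", d$level[i],
                  d$collection[i], d$n_cells[i],
                  if (isTRUE(d$skipped[i])) "passed through"
                  else sprintf("%d groups, %d pseudo-bulk, %d replicate sets, k = %d",
                               d$n_groups[i], d$n_pseudobulk[i], d$n_sets[i],
                               d$k_used[i])))
  }
  invisible(x)
}

#' @export
summary.fastruv <- function(object, ...) {
  out <- list(diagnostics = object$diagnostics,
              singular_values = lapply(object$models,
                                       function(m) m$singular_values),
              n_seg = vapply(object$models,
                             function(m) length(m$seg_indices), integer(1)))
  class(out) <- "summary.fastruv"
  out
}

#' @export
print.summary.fastruv <- function(x, ...) {
  cat("fastruv fit summary\n\nPer-collection diagnostics:\n")
  print(x$diagnostics)
  cat("\nLeading singular values of the replicate-residual pseudo-bulk:\n")
  for (nm in names(x$singular_values))
    cat(sprintf("  %s: %s\n", nm,
                paste(signif(utils::head(x$singular_values[[nm]], 5), 4),
                      collapse = ", ")))
  invisible(x)
}

#' Unwanted-variation loadings of a fit
#'
#' @param object a `fastruv` fit.
#' @param collection which fitted collection (default: the last one, i.e.
#'   the final merge level).
#' @param ... unused.
#' @return the k x genes loadings matrix alpha.
#' @export
coef.fastruv <- function(object, collection = length(object$models), ...) {
  if (!length(object$models)) return(NULL)
  object$models[[collection]]$alpha
}

#' Estimated unwanted component of the final model
#'
#' Returns `W alpha` of the final fitted collection on the standardized
#' scale — the component the last merge level subtracted.
#'
#' @param object a `fastruv` fit.
#' @param ... unused.
#' @export
residuals.fastruv <- function(object, ...) {
  if (!length(object$models)) return(NULL)
  m <- object$models[[length(object$models)]]
  m$W %*% m$alpha
}

#' Adjust new cells with an existing fit
#'
#' Applies the final fitted model to new data measured on the same genes:
#' the stored gene-wise standardization is applied, the per-cell unwanted
#' factors are regressed from the stored loadings restricted to the stored
#' SEG columns, and the unwanted component is subtracted.
#'
#' @param object a `fastruv` fit with at least one fitted collection.
#' @param newdata an [expression_data] (counts or log scale) with the same
#'   genes as the training data.
#' @param ... unused.
#' @return An [expression_data] of adjusted log-scale values.
#' @export
predict.fastruv <- function(object, newdata, ...) {
  if (!length(object$models)) fr_stop("fit has no adjusted collection")
  m <- object$models[[length(object$models)]]
  stopifnot(inherits(newdata, "expr_data"))
  if (!identical(newdata$gene_ids, m$gene_ids))
    fr_stop("newdata genes do not match the fitted model")
  ln <- if (newdata$scale == "counts")
    lognormalize(newdata, base = object$params$base) else newdata
  vals <- as_dense(ln$values)
  if (object$params$cosine) {
    vals <- cosine_normalize(vals)
    attr(vals, "cell_norms") <- NULL
  }
  div <- ifelse(m$stats$zero_variance_mask, 1, m$stats$gene_sds)
  z <- sweep(sweep(vals, 2, m$stats$gene_means, "-"), 2, div, "/")
  z[, m$stats$zero_variance_mask] <- 0
  W <- estimate_W(z, m$alpha, m$seg_indices)
  out <- unstandardize_genes(ruv_adjust(z, W, m$alpha), m$stats)
  expression_data(out, ln$metadata, gene_ids = ln$gene_ids,
                  cell_ids = ln$cell_ids, scale = "lognorm")
}

#' Scree plot of the replicate-residual singular values
#'
#' @param x a `fastruv` fit.
#' @param collection which fitted collection (default: last).
#' @param ... passed to [graphics::barplot()].
#' @export
plot.fastruv <- function(x, collection = length(x$models), ...) {
  if (!length(x$models)) fr_stop("fit has no adjusted collection")
  sv <- x$models[[collection]]$singular_values
  graphics::barplot(sv, names.arg = seq_along(sv),
                    xlab = "unwanted factor", ylab = "singular value", ...)
  invisible(x)
}
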