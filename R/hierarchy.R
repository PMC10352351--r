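## hierarchy module: multi-level merge trees. Each level holds disjoint
## collections of batches; within a collection the full pipeline (group ->
## pseudo-bulk -> replicates -> factor model -> adjust) runs with its own
## batch label and k; the adjusted matrix feeds the next level.

#' Define one collection of a merge-tree level
#'
#' @param members batch values (of `batch_column`) merged together.
#' @param name collection name (for diagnostics and error messages).
#' @param batch_column metadata column acting as the batch label at this
#'   level (e.g. cohort at level 1, study at level 2).
#' @param k_ruv,k_pseudobulk,per_condition optional per-collection overrides
#'   of the global parameters.
#' @export
merge_collection <- function(members, name = paste(members, collapse = "+"),
                             batch_column = "batch", k_ruv = NULL,
                             k_pseudobulk = NULL, per_condition = NULL) {
  structure(list(name = name, batch_column = batch_column,
                 members = as.character(members), k_ruv = k_ruv,
                 k_pseudobulk = k_pseudobulk, per_condition = per_condition),
            class = "merge_collection")
}

#' Build a merge tree
#'
#' @param ... one list of [merge_collection()]s per level, in execution
#'   order.
#' @export
merge_tree <- function(...) {
  levels <- list(...)
  for (lv in levels) {
    stopifnot(is.list(lv))
    for (col in lv) stopifnot(inherits(col, "merge_collection"))
  }
  structure(list(levels = levels), class = "merge_tree")
}

#' @export
print.merge_tree <- function(x, ...) {
  cat(sprintf("merge_tree: %d level(s)\n", length(x$levels)))
  for (li in seq_along(x$levels)) {
    for (col in x$levels[[li]])
      cat(sprintf("  level %d | %s [%s]: %s%s\n", li, col$name,
                  col$batch_column, paste(col$members, collapse = ", "),
                  if (!is.null(col$k_ruv)) sprintf(" (k_ruv = %d)", col$k_ruv) else ""))
  }
  invisible(x)
}

#' Read a merge-tree config from JSON or YAML
#'
#' The schema is a top-level `levels` array; each level is an array of
#' collections with fields `name`, `members`, and optional `batch_column`,
#' `k_ruv`, `k_pseudobulk`, `per_condition`. Two worked configs for a
#' two-study, three-cohorts-each CITE-seq integration ship in
#' `inst/extdata/` (`tree_rna.json` with `k_ruv = 10` at both levels,
#' `tree_adt.json` with `k_ruv = 3`).
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @export
read_merge_tree <- function(path) {
  if (!file.exists(path)) fr_stop("merge-tree config '%s' does not exist", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  if (is.null(raw$levels)) fr_stop("merge-tree config has no 'levels' field")
  levels <- lapply(raw$levels, function(lv) {
    lapply(lv, function(col) {
      if (is.null(col$members)) fr_stop("a collection has no 'members'")
      merge_collection(members = unlist(col$members),
                       name = col$name %||% paste(unlist(col$members), collapse = "+"),
                       batch_column = col$batch_column %||% "batch",
                       k_ruv = col$k_ruv, k_pseudobulk = col$k_pseudobulk,
                       per_condition = col$per_condition)
    })
  })
  do.call(merge_tree, levels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_tree <- function(tree, metadata) {
  stopifnot(inherits(tree, "merge_tree"))
  for (li in seq_along(tree$levels)) {
    lv <- tree$levels[[li]]
    seen <- character(0)
    for (col in lv) {
      if (!col$batch_column %in% names(metadata))
        fr_stop("level %d collection '%s': metadata has no column '%s'",
                li, col$name, col$batch_column)
      missing <- setdiff(col$members, unique(metadata[[col$batch_column]]))
      if (length(missing))
        fr_stop("level %d collection '%s': unknown batch value(s): %s",
                li, col$name, paste(missing, collapse = ", "))
      key <- paste(col$batch_column, col$members, sep = "=")
      if (length(intersect(key, seen)))
        fr_stop("level %d: collections overlap on %s", li,
                paste(intersect(key, seen), collapse = ", "))
      seen <- c(seen, key)
    }
  }
  invisible(TRUE)
}

## Internal: run the pipeline on one collection. `data` is on the (cosine-)
## log scale; `counts` (optional) is the raw count matrix aligned with
## `data`, needed only for pool-divide pseudo-bulk. Returns list(values,
## model, diagnostics) where `values` covers only the collection's cells.
run_collection_ <- function(data, counts, collection, seg, seed, params,
                            level_key) {
  b_col <- collection$batch_column
  eff_batch_all <- as.character(data$metadata[[b_col]])
  idx <- which(eff_batch_all %in% collection$members)
  if (!length(idx)) fr_stop("collection '%s' matches no cells", collection$name)
  k_ruv <- collection$k_ruv %||% params$k_ruv
  eff_batch <- eff_batch_all[idx]
  if (length(unique(eff_batch)) < 2) {
    fr_warn("collection '%s' has a single batch; passing through unadjusted",
            collection$name)
    return(list(values = NULL, model = NULL,
                diagnostics = data.frame(collection = collection$name,
                                         n_cells = length(idx), n_groups = NA,
                                         n_pseudobulk = NA, n_sets = NA,
                                         k_used = 0, skipped = TRUE)))
  }
  if (k_ruv == 0) {
    return(list(values = NULL, model = NULL,
                diagnostics = data.frame(collection = collection$name,
                                         n_cells = length(idx), n_groups = NA,
                                         n_pseudobulk = NA, n_sets = NA,
                                         k_used = 0, skipped = TRUE)))
  }
  md <- data$metadata[idx, , drop = FALSE]
  md$batch <- eff_batch                       # batch label at this level
  sub <- expression_data(as_dense(data$values[idx, , drop = FALSE]), md,
                         gene_ids = data$gene_ids,
                         cell_ids = data$cell_ids[idx], scale = "lognorm")
  std <- standardize_genes(sub$values)
  Z <- std$z

  hvg <- if (is.null(params$hvg_n) || ncol(Z) <= params$hvg_n) sub$gene_ids
         else select_hvg(sub, n = params$hvg_n)
  hvg_idx <- match(hvg, sub$gene_ids)

  grouping <- if (inherits(params$grouping, "cell_grouping")) {
    structure(list(labels = params$grouping$labels[idx],
                   source = params$grouping$source), class = "cell_grouping")
  } else if (is.character(params$grouping) && length(params$grouping) == 1) {
    adopt_labels(sub, params$grouping)
  } else {
    cluster_within_batch(sub, hvg, n_neighbors = params$n_neighbors,
                         seed = stage_seed(seed, level_key, "grouping"),
                         resolution = params$resolution)
  }

  k_pb <- collection$k_pseudobulk %||% params$k_pseudobulk
  strategy <- params$strategy
  pb_seed <- stage_seed(seed, level_key, "pseudobulk")
  if (strategy == "mean_random_split") {
    pb <- construct_pseudobulk(Z, grouping, md, k = k_pb, strategy = strategy,
                               seed = pb_seed)
  } else {
    if (is.null(counts))
      fr_stop("collection '%s': pool-divide pseudo-bulk requires count input",
              collection$name)
    pbc <- construct_pseudobulk(counts[idx, , drop = FALSE], grouping, md,
                                k = k_pb, strategy = strategy, seed = pb_seed,
                                counts = TRUE,
                                nb_dispersion = params$nb_dispersion)
    ## normalize pooled sums like cells, then map onto Z's scale
    lib <- rowSums(pbc$values)
    s <- lib / mean(lib[lib > 0]); s[lib == 0] <- 1
    lg <- log(pbc$values / s + 1, base = params$base)
    lg <- cosine_normalize(lg)
    zb <- sweep(sweep(lg, 2, std$stats$gene_means, "-"), 2,
                ifelse(std$stats$zero_variance_mask, 1, std$stats$gene_sds), "/")
    zb[, std$stats$zero_variance_mask] <- 0
    pb <- pbc
    pb$values <- zb
  }

  per_cond <- collection$per_condition %||% params$per_condition
  per_cond <- isTRUE(per_cond) && length(unique(md$condition)) > 1
  graph <- build_mnc_graph(pb, features = hvg_idx, per_condition = per_cond,
                           metric = params$mnc_metric)
  M <- replicate_sets_from_graph(graph, pb)

  af <- estimate_alpha(pb$values, M, k = k_ruv)
  seg_idx <- select_seg_indices(sub, seg = seg,
                                zero_variance_mask = std$stats$zero_variance_mask,
                                quantile = params$seg_quantile)
  W <- estimate_W(Z, af$alpha, seg_idx)
  adj <- ruv_adjust(Z, W, af$alpha)
  out <- unstandardize_genes(adj, std$stats)

  model <- structure(list(alpha = af$alpha, W = W, k = af$k,
                          seg_indices = seg_idx,
                          singular_values = af$singular_values,
                          stats = std$stats, gene_ids = sub$gene_ids,
                          collection = collection$name),
                     class = "ruv_model")
  diagnostics <- data.frame(collection = collection$name,
                            n_cells = length(idx),
                            n_groups = length(unique(grouping$labels)),
                            n_pseudobulk = nrow(pb$values),
                            n_sets = M$n_sets, k_used = af$k, skipped = FALSE)
  list(values = out, idx = idx, model = model, diagnostics = diagnostics)
}

#' Run one merge-tree collection
#'
#' Runs the complete pipeline (standardize on the collection's cells ->
#' grouping -> pseudo-bulk -> mutual-nearest-cluster replicates -> factor
#' model -> adjust -> inverse standardization) on the cells whose
#' `batch_column` value is in the collection's members. Cells outside the
#' collection are untouched. A collection with a single batch, or with
#' `k_ruv = 0`, passes through unadjusted.
#'
#' @param data an [expression_data] on the log scale.
#' @param collection a [merge_collection()].
#' @param seg optional SEG gene-ID vector.
#' @param seed integer seed.
#' @param params parameter list as produced by [fastruv_params()].
#' @param counts optional raw count matrix aligned with `data` (pool-divide
#'   strategies only).
#' @return list with the updated [expression_data], the fitted `ruv_model`
#'   (NULL when passed through) and a one-row diagnostics data.frame.
#' @export
run_collection <- function(data, collection, seg = NULL, seed = 1,
                           params = fastruv_params(), counts = NULL) {
  stopifnot(inherits(data, "expr_data"))
  res <- tryCatch(
    run_collection_(data, counts, collection, seg, seed, params,
                    level_key = "level1.1"),
    error = function(e) fr_stop("collection '%s': %s", collection$name,
                                conditionMessage(e)))
  if (!is.null(res$values)) data$values[res$idx, ] <- res$values
  list(data = data, model = res$model, diagnostics = res$diagnostics)
}

#' Run a full merge tree
#'
#' Executes the levels sequentially; each level's adjusted matrix is the next
#' level's input. Cell and gene order are preserved, and a one-level,
#' one-collection tree is bit-identical to the flat run with the same seed.
#'
#' @inheritParams run_collection
#' @param tree a [merge_tree()]; an empty tree returns the input unchanged
#'   with a warning.
#' @return list with `data` (adjusted [expression_data]), `models` (per
#'   collection), `diagnostics` (data.frame with one row per collection).
#' @export
run_tree <- function(data, tree, seg = NULL, seed = 1,
                     params = fastruv_params(), counts = NULL) {
  stopifnot(inherits(data, "expr_data"), inherits(tree, "merge_tree"))
  if (!length(tree$levels)) {
    fr_warn("empty merge tree; returning input unchanged")
    return(list(data = data, models = list(), diagnostics = NULL))
  }
  validate_tree(tree, data$metadata)
  models <- list()
  diags <- list()
  for (li in seq_along(tree$levels)) {
    for (ci in seq_along(tree$levels[[li]])) {
      col <- tree$levels[[li]][[ci]]
      res <- tryCatch(
        run_collection_(data, counts, col, seg, seed, params,
                        level_key = sprintf("level%d.%d", li, ci)),
        error = function(e) fr_stop("level %d, collection '%s': %s", li,
                                    col$name, conditionMessage(e)))
      if (!is.null(res$values)) data$values[res$idx, ] <- res$values
      if (!is.null(res$model)) models[[paste0("L", li, ".", col$name)]] <- res$model
      d <- res$diagnostics
      d$level <- li
      diags[[length(diags) + 1L]] <- d
    }
  }
  list(data = data, models = models, diagnostics = do.call(rbind, diags))
}
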