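## evaluate module: integration-quality metrics (ARI, silhouette width, PCA
## scores) and downstream differential-state testing on sample-aggregated
## pseudo-bulk with FDR/TPR/F1 scoring against simulation truth.

#' Top principal components of an expression matrix
#'
#' Column-centered truncated PCA. Returns the scores and the fraction of
#' total variance explained by each component. `d` is clamped (with a
#' warning) when the matrix has fewer than `d` usable dimensions.
#'
#' @param m cells x genes matrix (or an [expression_data]).
#' @param d number of components (default 20).
#' @export
pca_embed <- function(m, d = 20) {
  if (inherits(m, "expr_data")) m <- m$values
  m <- as_dense(m)
  dmax <- min(dim(m)) - 1
  if (d > dmax) {
    fr_warn("requested %d PCs but only %d available; clamping", d, dmax)
    d <- dmax
  }
  mc <- sweep(m, 2, colMeans(m), "-")
  total_var <- sum(colSums(mc^2)) / (nrow(m) - 1)
  sv <- if (d < dmax / 3 && min(dim(m)) > 50) {
    irlba::irlba(mc, nv = d)
  } else {
    s <- svd(mc, nu = d, nv = d)
    list(u = s$u, d = s$d[seq_len(d)], v = s$v)
  }
  scores <- sv$u %*% diag(sv$d, d, d)
  list(scores = scores, var_fraction = sv$d^2 / ((nrow(m) - 1) * total_var))
}

#' Cluster an adjusted matrix for ARI evaluation
#'
#' Embeds the matrix in its top 20 PCs, builds a shared-nearest-neighbour
#' graph (10 neighbours) and runs Louvain clustering — the standard recipe
#' for judging integration output by clustering concordance.
#'
#' @param data an [expression_data] (or plain matrix).
#' @param seed integer seed.
#' @param n_pcs,n_neighbors embedding and graph parameters.
#' @return integer cluster labels, one per cell.
#' @export
cluster_for_ari <- function(data, seed = 1, n_pcs = 20, n_neighbors = 10) {
  emb <- pca_embed(data, d = n_pcs)$scores
  louvain_cluster(emb, n_neighbors, stage_seed(seed, "eval-cluster"))
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement of two partitions of the same elements;
#' invariant to label permutation. 1 for identical partitions, ~0 for
#' independent ones.
#'
#' @param p1,p2 two label vectors of equal length.
#' @export
ari <- function(p1, p2) {
  if (length(p1) != length(p2)) fr_stop("partitions have different lengths")
  tab <- table(p1, p2)
  n <- length(p1)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  c_ <- sum(choose(colSums(tab), 2))
  expected <- b * c_ / choose(n, 2)
  denom <- (b + c_) / 2 - expected
  if (denom == 0) return(1)                    # both partitions trivial
  (a - expected) / denom
}

#' Average silhouette width
#'
#' Mean silhouette coefficient over points (Euclidean distance). By default
#' the caller passes a deterministic top-PC embedding; a 2-D UMAP embedding
#' (as used in visual benchmarking) can be supplied instead. Points in
#' singleton clusters contribute 0.
#'
#' @param embedding points x dims numeric matrix.
#' @param labels grouping labels (at least 2 distinct values).
#' @export
asw <- function(embedding, labels) {
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2) fr_stop("asw needs at least 2 label levels")
  sil <- cluster::silhouette(labels, stats::dist(embedding))
  mean(sil[, "sil_width"])
}

#' PCA score of a technical label
#'
#' For each of the first 20 PCs, the coefficient of determination (R^2) of
#' the PC scores regressed on the label's one-hot indicators is weighted by
#' that PC's variance-explained fraction and summed. The score quantifies how
#' much of the principal variation the technical label explains; lower means
#' better removal of unwanted variation.
#'
#' @param data an [expression_data] or matrix.
#' @param label technical label per cell (>= 2 levels).
#' @param n_pcs number of components (default 20).
#' @export
pca_score <- function(data, label, n_pcs = 20) {
  label <- as.factor(label)
  if (nlevels(label) < 2) fr_stop("pca_score needs a label with >= 2 levels")
  emb <- pca_embed(data, d = n_pcs)
  r2 <- apply(emb$scores, 2, function(y) {
    mu <- mean(y)
    ss_between <- sum(tapply(y, label, function(v) length(v) * (mean(v) - mu)^2))
    ss_total <- sum((y - mu)^2)
    if (ss_total == 0) 0 else ss_between / ss_total
  })
  sum(emb$var_fraction * r2)
}

#' Differential-state test on sample-aggregated pseudo-bulk
#'
#' For each cell type, cells are aggregated to gene x sample means, and each
#' gene is tested between the two conditions with a moderated linear-model
#' t-test in which residual variances are shrunk toward a smooth trend of
#' log-variance against mean expression (the limma-trend approach).
#' Benjamini-Hochberg correction is applied within each cell type by default.
#'
#' @param data an [expression_data] on the log scale.
#' @param celltype,sample,condition per-cell label vectors; default to the
#'   metadata columns of `data`.
#' @param min_samples minimum samples per condition per cell type (cell types
#'   below it are skipped with a warning).
#' @param global_correction apply BH across all cell types jointly instead.
#' @return data.frame with columns `cell_type`, `gene`, `logFC`, `t`, `p`,
#'   `padj`.
#' @export
ds_test <- function(data, celltype = data$metadata$cell_type,
                    sample = data$metadata$sample,
                    condition = data$metadata$condition,
                    min_samples = 2, global_correction = FALSE) {
  stopifnot(inherits(data, "expr_data"))
  if (is.null(celltype)) fr_stop("no cell-type labels available")
  cond_levels <- sort(unique(condition))
  if (length(cond_levels) != 2)
    fr_stop("ds_test requires exactly 2 conditions, found %d", length(cond_levels))
  res <- list()
  for (ct in sort(unique(celltype))) {
    idx <- which(celltype == ct)
    sm <- sample[idx]
    agg <- rowsum(as_dense(data$values[idx, , drop = FALSE]), sm) /
      as.vector(table(sm))
    s_cond <- condition[idx][match(rownames(agg), sm)]
    if (min(table(factor(s_cond, levels = cond_levels))) < min_samples) {
      fr_warn("cell type '%s' has fewer than %d samples in a condition; skipped",
              ct, min_samples)
      next
    }
    design <- stats::model.matrix(~ factor(s_cond, levels = cond_levels))
    fit <- limma::lmFit(t(agg), design)
    fit <- limma::eBayes(fit, trend = TRUE)
    tt <- limma::topTable(fit, coef = 2, number = Inf, sort.by = "none")
    res[[ct]] <- data.frame(cell_type = ct, gene = data$gene_ids,
                            logFC = tt$logFC, t = tt$t, p = tt$P.Value,
                            padj = tt$adj.P.Val, stringsAsFactors = FALSE)
  }
  if (!length(res)) fr_stop("no cell type had enough samples for testing")
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (global_correction) out$padj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Score differential-state calls against simulation truth
#'
#' Confusion-matrix metrics per cell type at each adjusted-p threshold. With
#' zero calls, FDR and F1 are defined as 0.
#'
#' @param calls output of [ds_test()].
#' @param truth a `sim_truth` (see [simulate_counts()]).
#' @param alpha_levels BH thresholds (default 0.05).
#' @return data.frame with `cell_type`, `alpha`, `FDR`, `TPR`, `F1`, call and
#'   truth counts.
#' @export
score_ds <- function(calls, truth, alpha_levels = 0.05) {
  stopifnot(inherits(truth, "sim_truth"))
  out <- list()
  for (ct in sort(unique(calls$cell_type))) {
    sub <- calls[calls$cell_type == ct, ]
    true_genes <- truth$ds$gene[truth$ds$cell_type == ct]
    for (a in alpha_levels) {
      called <- sub$gene[sub$padj < a]
      tp <- length(intersect(called, true_genes))
      fp <- length(called) - tp
      fn <- length(setdiff(true_genes, called))
      fdr <- if (length(called)) fp / length(called) else 0
      tpr <- if (length(true_genes)) tp / length(true_genes) else 0
      f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
      out[[length(out) + 1L]] <-
        data.frame(cell_type = ct, alpha = a, FDR = fdr, TPR = tpr, F1 = f1,
                   n_called = length(called), n_true = length(true_genes))
    }
  }
  do.call(rbind, out)
}

#' Integration quality scores
#'
#' Convenience wrapper computing the standard signal-to-noise panel on one
#' matrix: ARI and ASW of a Louvain clustering / top-PC embedding against
#' cell-type labels (signal, higher is better) and batch labels (noise, lower
#' is better), plus the batch PCA score.
#'
#' @param data an [expression_data] with `batch` (and ideally `cell_type`)
#'   metadata.
#' @param seed integer seed for the evaluation clustering.
#' @return one-row data.frame: `ari_celltype`, `ari_batch`, `asw_celltype`,
#'   `asw_batch`, `pca_batch`.
#' @export
integration_scores <- function(data, seed = 1) {
  stopifnot(inherits(data, "expr_data"))
  emb <- pca_embed(data, d = 20)$scores
  part <- cluster_for_ari(data, seed = seed)
  ct <- data$metadata$cell_type
  batch <- data$metadata$batch
  data.frame(
    ari_celltype = if (!is.null(ct)) ari(part, ct) else NA_real_,
    ari_batch = ari(part, batch),
    asw_celltype = if (!is.null(ct)) asw(emb, ct) else NA_real_,
    asw_batch = asw(emb, batch),
    pca_batch = pca_score(data, batch)
  )
}
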