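## ruviii module: the factor model Z = X beta + W alpha + eps. alpha is
## estimated from the replicate-residual SVD of the pseudo-bulk sketch, W on
## the full standardized matrix via stably expressed genes (negative
## controls), and the unwanted component W alpha is subtracted.

#' Residual operator of the replicate structure
#'
#' Computes `R_M Z` where `R_M = I - M (M'M)^{-1} M'` is the orthogonal
#' projector onto the complement of the replicate-set design: each row of `Z`
#' has its replicate-set mean subtracted. The C x C projector is never
#' materialized. Rows in singleton sets become exactly zero.
#'
#' @param Z observations x genes matrix.
#' @param M a `replicate_matrix` (or a vector of set labels).
#' @export
residual_center <- function(Z, M) {
  if (!inherits(M, "replicate_matrix")) M <- replicate_matrix(M)
  Z <- as_dense(Z)
  if (nrow(Z) != length(M$sets))
    fr_stop("Z has %d rows but the replicate matrix describes %d observations",
            nrow(Z), length(M$sets))
  sizes <- tabulate(M$sets, nbins = M$n_sets)
  means <- rowsum(Z, M$sets) / sizes           # set order = 1..N_b
  out <- Z - means[M$sets, , drop = FALSE]
  dimnames(out) <- dimnames(Z)
  out
}

#' Estimate the unwanted-variation loadings alpha
#'
#' alpha is the matrix of the first `k` right singular vectors (as rows) of
#' the replicate-residual matrix `R_M Z`. Rows are unit-norm; singular values
#' are absorbed into W by the later regression step. If the residual matrix
#' has rank `r < k`, alpha is truncated to `r` rows with a warning. The sign
#' of each row is fixed so its largest-magnitude entry is positive, making
#' results stable across linear-algebra backends.
#'
#' @param Zb observations x genes matrix (typically the pseudo-bulk sketch on
#'   the standardized scale).
#' @param M a `replicate_matrix` over the rows of `Zb`.
#' @param k number of unwanted factors. Defaults in the field: 20 for
#'   scRNA-seq, 10 for ADT/CyTOF panels.
#' @return list with `alpha` (k x G, orthonormal rows), `singular_values`,
#'   and `k` actually used.
#' @export
estimate_alpha <- function(Zb, M, k = 20) {
  stopifnot(k >= 1)
  R <- residual_center(Zb, M)
  sv <- svd(R)
  tol <- max(dim(R)) * max(sv$d) * .Machine$double.eps
  r <- sum(sv$d > max(tol, 0))
  if (r == 0)
    fr_stop("no within-replicate variation to estimate unwanted factors")
  if (r < k) {
    fr_warn("requested k = %d but residual matrix has rank %d; truncating", k, r)
    k <- r
  }
  alpha <- t(sv$v[, seq_len(k), drop = FALSE])
  ## deterministic sign: largest-magnitude entry of each row positive
  for (i in seq_len(k)) {
    j <- which.max(abs(alpha[i, ]))
    if (alpha[i, j] < 0) alpha[i, ] <- -alpha[i, ]
  }
  list(alpha = alpha, singular_values = sv$d[seq_len(k)], k = k)
}

#' Estimate the per-cell unwanted factors W from negative-control genes
#'
#' Restricts `Z` and `alpha` to the stably-expressed-gene (SEG) columns and
#' solves the least-squares problem `W = Z_s alpha_s' (alpha_s alpha_s')^{-1}`.
#' SEGs act as negative controls: their variation across cells is attributed
#' to unwanted factors only. A pseudo-inverse is used (with a warning) when
#' `alpha_s alpha_s'` is ill-conditioned.
#'
#' @param Z cells x genes standardized matrix.
#' @param alpha k x genes loadings from [estimate_alpha()].
#' @param seg_indices integer indices of the SEG columns.
#' @param cond_tol condition-number threshold for switching to the
#'   pseudo-inverse (default 1e10).
#' @return C x k matrix W.
#' @export
estimate_W <- function(Z, alpha, seg_indices, cond_tol = 1e10) {
  if (!length(seg_indices)) fr_stop("empty SEG set")
  Z <- as_dense(Z)
  As <- alpha[, seg_indices, drop = FALSE]
  Zs <- Z[, seg_indices, drop = FALSE]
  if (all(col_vars(Zs) == 0) && all(colMeans(Zs) == 0))
    fr_stop("all SEG columns are zero-variance; cannot estimate W")
  G <- As %*% t(As)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > cond_tol) {
    fr_warn("alpha restricted to SEG columns is ill-conditioned; using pseudo-inverse")
    Ginv <- MASS::ginv(G)
  } else {
    Ginv <- solve(G)
  }
  Zs %*% t(As) %*% Ginv
}

#' Subtract the estimated unwanted component
#'
#' Returns `Z - W alpha`. With `k = 0` (empty `W`, `alpha`) the input is
#' returned exactly.
#'
#' @param Z cells x genes matrix.
#' @param W C x k factor matrix.
#' @param alpha k x genes loadings.
#' @export
ruv_adjust <- function(Z, W, alpha) {
  Z <- as_dense(Z)
  if (is.null(W) || is.null(alpha) || ncol(as.matrix(W)) == 0 ||
      nrow(as.matrix(alpha)) == 0) return(Z)
  Z - W %*% alpha
}

#' Heuristic per-gene stability score
#'
#' A fallback for when no stably-expressed-gene list is supplied: each gene
#' is scored by the average of (a) the rank of its expression proportion
#' (fraction of cells with nonzero expression, higher is more stable) and
#' (b) the rank of its residual variance after removing batch means (lower is
#' more stable), scaled to (0, 1]. This heuristic is *not* the published SEG
#' derivation; a curated SEG list, when available, is the recommended input.
#'
#' @param data an [expression_data] on the log scale.
#' @return numeric vector of scores, names = gene IDs; higher = more stable.
#' @export
compute_seg_scores <- function(data) {
  stopifnot(inherits(data, "expr_data"))
  if (length(unique(data$metadata$batch)) < 2)
    fr_stop("stability scores need at least 2 batches")
  m <- as_dense(data$values)
  prop <- colMeans(m > 0)
  batch <- data$metadata$batch
  means <- rowsum(m, batch) / as.vector(table(batch))
  resid <- m - means[batch, , drop = FALSE]
  resvar <- colSums(resid^2) / max(1, nrow(m) - length(unique(batch)))
  score <- (rank(prop, ties.method = "average") +
            rank(-resvar, ties.method = "average")) / (2 * ncol(m))
  stats::setNames(score, data$gene_ids)
}

#' Pick a SEG index set
#'
#' Uses a user-supplied gene list when given (unmatched entries reported),
#' otherwise falls back to the top quantile of [compute_seg_scores()].
#' Zero-variance genes are always excluded.
#'
#' @param data an [expression_data] on the log scale.
#' @param seg optional character vector of SEG gene IDs (e.g. read from a
#'   one-ID-per-line file).
#' @param zero_variance_mask logical mask of zero-variance genes to exclude.
#' @param quantile fraction of genes kept by the fallback heuristic
#'   (default 0.2).
#' @return integer vector of gene column indices.
#' @export
select_seg_indices <- function(data, seg = NULL, zero_variance_mask = NULL,
                               quantile = 0.2) {
  if (!is.null(seg)) {
    unmatched <- setdiff(seg, data$gene_ids)
    if (length(unmatched))
      fr_warn("%d SEG entr%s not found in gene_ids (first: %s)",
              length(unmatched), if (length(unmatched) == 1) "y" else "ies",
              paste(utils::head(unmatched, 5), collapse = ", "))
    idx <- match(intersect(seg, data$gene_ids), data$gene_ids)
  } else {
    score <- compute_seg_scores(data)
    idx <- which(score >= stats::quantile(score, 1 - quantile))
  }
  if (!is.null(zero_variance_mask)) idx <- idx[!zero_variance_mask[idx]]
  if (!length(idx)) fr_stop("SEG set is empty after filtering")
  sort(idx)
}

#' Read a SEG list (one gene ID per line)
#'
#' @param path text file with one gene identifier per line.
#' @export
read_seg_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  unique(x[nzchar(x)])
}
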