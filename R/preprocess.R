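## preprocess module: from raw counts to the standardized matrix Z that the
## RUV-III model consumes: size-factor log-normalization, cosine
## normalization, gene-wise standardization, batch-blocked HVG selection.

#' Size-factor log-normalization
#'
#' Per-cell size factors are library sizes divided by their mean; the output
#' is `log2(count / s + 1)` (base configurable). Cells with zero library size
#' get size factor 1, hence an all-zero row.
#'
#' @param data an [expression_data] with `scale = "counts"`.
#' @param base logarithm base (default 2).
#' @return An [expression_data] with `scale = "lognorm"`.
#' @export
lognormalize <- function(data, base = 2) {
  stopifnot(inherits(data, "expr_data"))
  if (data$scale != "counts") fr_stop("lognormalize() expects count-scale data")
  v <- data$values
  lib <- if (inherits(v, "Matrix")) Matrix::rowSums(v) else rowSums(v)
  if (any(lib < 0)) fr_stop("negative counts encountered")
  mean_lib <- mean(lib[lib > 0])
  if (!is.finite(mean_lib)) mean_lib <- 1
  s <- lib / mean_lib
  s[lib == 0] <- 1
  out <- as_dense(v) / s                 # recycles by row
  out <- log(out + 1, base = base)
  expression_data(out, data$metadata, gene_ids = data$gene_ids,
                  cell_ids = data$cell_ids, scale = "lognorm")
}

#' Cosine normalization of a cells x genes matrix
#'
#' Divides each nonzero row by its L2 norm; zero rows pass through. Returns
#' the matrix with the pre-normalization norms in attribute `"cell_norms"`.
#'
#' @param m numeric matrix, rows = cells.
#' @export
cosine_normalize <- function(m) {
  m <- as_dense(m)
  nrm <- sqrt(rowSums(m^2))
  div <- ifelse(nrm > 0, nrm, 1)
  out <- m / div
  attr(out, "cell_norms") <- nrm
  out
}

#' Gene-wise standardization
#'
#' Centers and scales each gene (column) using the sample standard deviation
#' (n-1 denominator). Zero-variance genes become all-zero columns and are
#' flagged so that downstream adjustment leaves them untouched and the
#' inverse transform restores them verbatim.
#'
#' @param m numeric matrix, rows = cells, columns = genes.
#' @return list with `z` (standardized matrix) and `stats`, a
#'   `standardization_stats` object holding `gene_means`, `gene_sds`,
#'   `zero_variance_mask` and any `cell_norms` attribute found on `m`.
#' @export
standardize_genes <- function(m) {
  m <- as_dense(m)
  mu <- colMeans(m)
  sd <- sqrt(col_vars(m))
  zero <- sd == 0
  div <- ifelse(zero, 1, sd)
  z <- sweep(sweep(m, 2, mu, "-"), 2, div, "/")
  z[, zero] <- 0
  stats <- structure(list(gene_means = mu, gene_sds = sd,
                          zero_variance_mask = zero,
                          cell_norms = attr(m, "cell_norms")),
                     class = "standardization_stats")
  list(z = z, stats = stats)
}

#' Invert gene-wise standardization
#'
#' Maps an adjusted standardized matrix back to the (cosine-normalized) log
#' scale: multiply by the stored gene standard deviation and add the gene
#' mean. Zero-variance genes are restored to their original constant values.
#'
#' @param z standardized matrix.
#' @param stats a `standardization_stats` object from [standardize_genes()].
#' @export
unstandardize_genes <- function(z, stats) {
  out <- sweep(sweep(z, 2, stats$gene_sds, "*"), 2, stats$gene_means, "+")
  zv <- stats$zero_variance_mask
  if (any(zv)) out[, zv] <- rep(stats$gene_means[zv], each = nrow(out))
  out
}

#' Select highly variable genes, blocked by batch
#'
#' Within each batch a local-polynomial trend (loess, span 0.3) of per-gene
#' variance against per-gene mean is fitted on the log scale and genes are
#' scored by residual variance. Residual ranks are averaged across batches
#' and the top `n` genes returned, ties broken by gene ID. If there are at
#' most `n` genes (low-feature modalities such as ADT or CyTOF panels) all
#' genes are returned.
#'
#' @param data an [expression_data] on the log scale.
#' @param n number of genes to keep (default 2000).
#' @param span loess span for the mean-variance trend.
#' @return character vector of gene IDs.
#' @export
select_hvg <- function(data, n = 2000, span = 0.3) {
  stopifnot(inherits(data, "expr_data"), n >= 1)
  G <- ncol(data$values)
  if (G <= n) return(data$gene_ids)
  batches <- unique(data$metadata$batch)
  rank_sum <- numeric(G)
  for (b in batches) {
    idx <- which(data$metadata$batch == b)
    if (length(idx) < 2)
      fr_stop("batch '%s' has fewer than 2 cells; cannot estimate variances", b)
    m <- as_dense(data$values[idx, , drop = FALSE])
    mu <- colMeans(m)
    v <- col_vars(m)
    ## loess can be numerically noisy on degenerate mean-variance clouds;
    ## fall back to a flat trend if it fails outright
    resid <- tryCatch({
      fit <- suppressWarnings(stats::loess(v ~ mu, span = span, degree = 2,
                                           family = "symmetric"))
      v - suppressWarnings(stats::predict(fit, mu))
    }, error = function(e) v - mean(v))
    resid[is.na(resid)] <- 0
    ## descending residual variance -> rank 1 is the most variable
    rank_sum <- rank_sum + rank(-resid, ties.method = "average")
  }
  avg_rank <- rank_sum / length(batches)
  ord <- order(avg_rank, data$gene_ids)
  data$gene_ids[ord[seq_len(n)]]
}

#' Full preprocessing chain
#'
#' Counts are log-normalized (skipped when the input is already on the log
#' scale), cosine-normalized and gene-wise standardized.
#'
#' @param data an [expression_data] (`counts` or `lognorm`).
#' @param base log base for normalization.
#' @param cosine apply cosine normalization (default TRUE).
#' @return list with `lognorm` (an [expression_data]), `z` (standardized
#'   matrix) and `stats` (a `standardization_stats`).
#' @export
preprocess <- function(data, base = 2, cosine = TRUE) {
  ln <- if (data$scale == "counts") lognormalize(data, base = base) else data
  m <- as_dense(ln$values)
  if (cosine) m <- cosine_normalize(m)
  std <- standardize_genes(m)
  list(lognorm = ln, z = std$z, stats = std$stats)
}
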