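## io module: validated expression container plus readers/writers for the
## standard on-disk formats (MatrixMarket triplet, dense CSV, HDF5).

#' Construct a validated expression data object
#'
#' The central container of the package: a cells x genes expression matrix
#' (dense or sparse) together with per-cell metadata. Every cell must carry a
#' batch and a sample label; `condition` and `cell_type` are optional. When no
#' condition column is present all cells are assigned the single token
#' `"__all__"`, so condition-aware downstream steps degenerate to the
#' unconditional path.
#'
#' @param values numeric matrix (or `Matrix` sparse matrix), rows = cells,
#'   columns = genes.
#' @param metadata data.frame with one row per cell; must contain columns
#'   `batch` and `sample`; may contain `condition` and `cell_type`.
#' @param gene_ids,cell_ids character vectors of unique identifiers; default
#'   to the dimnames of `values`.
#' @param scale one of `"counts"`, `"lognorm"`, `"standardized"`.
#' @return An object of class `expr_data` with elements `values`, `gene_ids`,
#'   `cell_ids`, `scale`, `metadata`.
#' @examples
#' m <- matrix(rpois(6, 5), 3, 2, dimnames = list(paste0("c", 1:3), c("g1", "g2")))
#' md <- data.frame(batch = "b1", sample = c("s1", "s1", "s2"))
#' x <- expression_data(m, md)
#' dim(x)
#' @export
expression_data <- function(values, metadata,
                            gene_ids = colnames(values),
                            cell_ids = rownames(values),
                            scale = c("counts", "lognorm", "standardized")) {
  scale <- match.arg(scale)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(values)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(values)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != ncol(values))
    fr_stop("length of gene_ids (%d) does not match number of matrix columns (%d)",
            length(gene_ids), ncol(values))
  if (length(cell_ids) != nrow(values))
    fr_stop("length of cell_ids (%d) does not match number of matrix rows (%d)",
            length(cell_ids), nrow(values))
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g))
    fr_stop("duplicate gene_ids: %s", paste(utils::head(dup_g, 10), collapse = ", "))
  dup_c <- unique(cell_ids[duplicated(cell_ids)])
  if (length(dup_c))
    fr_stop("duplicate cell_ids: %s", paste(utils::head(dup_c, 10), collapse = ", "))
  metadata <- as.data.frame(metadata)
  if (nrow(metadata) != nrow(values))
    fr_stop("metadata has %d rows but the matrix has %d cells",
            nrow(metadata), nrow(values))
  for (col in c("batch", "sample")) {
    if (!col %in% names(metadata))
      fr_stop("metadata is missing required column '%s'", col)
    if (anyNA(metadata[[col]]))
      fr_stop("metadata column '%s' has missing values", col)
    metadata[[col]] <- as.character(metadata[[col]])
  }
  if (!"condition" %in% names(metadata)) {
    metadata$condition <- "__all__"
  } else {
    if (anyNA(metadata$condition))
      fr_stop("metadata column 'condition' has missing values")
    metadata$condition <- as.character(metadata$condition)
  }
  if ("cell_type" %in% names(metadata))
    metadata$cell_type <- as.character(metadata$cell_type)
  ## every sample maps to exactly one batch and one condition
  smap <- unique(metadata[, c("sample", "batch")])
  bad <- smap$sample[duplicated(smap$sample)]
  if (length(bad))
    fr_stop("sample(s) assigned to more than one batch: %s",
            paste(unique(bad), collapse = ", "))
  cmap <- unique(metadata[, c("sample", "condition")])
  bad <- cmap$sample[duplicated(cmap$sample)]
  if (length(bad))
    fr_stop("sample(s) assigned to more than one condition: %s",
            paste(unique(bad), collapse = ", "))
  if (scale == "counts") {
    mn <- if (inherits(values, "Matrix")) min(values@x, 0) else min(values)
    if (is.finite(mn) && mn < 0) fr_stop("scale = 'counts' but matrix has negative values")
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  rownames(metadata) <- cell_ids
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 scale = scale, metadata = metadata),
            class = "expr_data")
}

#' @export
dim.expr_data <- function(x) dim(x$values)

#' @export
print.expr_data <- function(x, ...) {
  cat(sprintf("expr_data: %d cells x %d genes (scale: %s)\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  batches: %s\n", paste(unique(x$metadata$batch), collapse = ", ")))
  cat(sprintf("  samples: %d; conditions: %s\n",
              length(unique(x$metadata$sample)),
              paste(unique(x$metadata$condition), collapse = ", ")))
  invisible(x)
}

## Internal: subset by cell index, keeping metadata aligned.
subset_cells <- function(x, idx) {
  expression_data(x$values[idx, , drop = FALSE], x$metadata[idx, , drop = FALSE],
                  gene_ids = x$gene_ids, cell_ids = x$cell_ids[idx], scale = x$scale)
}

read_metadata_table <- function(metadata_path, cell_ids) {
  md <- utils::read.delim(metadata_path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if ("cell_id" %in% names(md)) {
    if (nrow(md) != length(cell_ids))
      fr_stop("metadata file '%s' has %d rows but the matrix has %d cells",
              metadata_path, nrow(md), length(cell_ids))
    mi <- match(cell_ids, md$cell_id)
    if (anyNA(mi))
      fr_stop("metadata file '%s' is missing cell ids: %s", metadata_path,
              paste(utils::head(cell_ids[is.na(mi)], 10), collapse = ", "))
    md <- md[mi, setdiff(names(md), "cell_id"), drop = FALSE]
  } else if (nrow(md) != length(cell_ids)) {
    fr_stop("metadata file '%s' has %d rows but the matrix has %d cells",
            metadata_path, nrow(md), length(cell_ids))
  }
  md
}

#' Read an expression matrix with per-cell metadata
#'
#' Supports the three community formats: MatrixMarket sparse triplets with
#' sidecar `features.tsv` / `barcodes.tsv` (genes x cells on disk, transposed
#' on load), dense CSV (header row = gene IDs, first column = cell IDs), and
#' HDF5 (datasets `/matrix`, `/gene_ids`, `/cell_ids`). Metadata is a TSV with
#' a header; if it has a `cell_id` column rows are matched by ID, otherwise
#' they are assumed to be in matrix order.
#'
#' @param path matrix file (CSV/HDF5) or directory containing `matrix.mtx`,
#'   `features.tsv`, `barcodes.tsv` (MTX).
#' @param format one of `"mtx"`, `"csv"`, `"hdf5"`.
#' @param metadata_path TSV file of per-cell metadata (columns `batch`,
#'   `sample`, optionally `condition`, `cell_type`).
#' @param scale scale of the stored values (default `"counts"`).
#' @return An [expression_data] object. Sparse inputs stay sparse.
#' @export
read_expression <- function(path, format = c("mtx", "csv", "hdf5"),
                            metadata_path,
                            scale = c("counts", "lognorm", "standardized")) {
  format <- match.arg(format)
  scale <- match.arg(scale)
  if (!file.exists(path)) fr_stop("input path '%s' does not exist", path)
  if (!file.exists(metadata_path)) fr_stop("metadata file '%s' does not exist", metadata_path)
  if (format == "mtx") {
    dir <- if (dir.exists(path)) path else dirname(path)
    mtx_file <- if (dir.exists(path)) file.path(path, "matrix.mtx") else path
    feat_file <- file.path(dir, "features.tsv")
    bc_file <- file.path(dir, "barcodes.tsv")
    for (f in c(mtx_file, feat_file, bc_file))
      if (!file.exists(f)) fr_stop("expected file '%s' is missing", f)
    m <- Matrix::readMM(mtx_file)           # genes x cells on disk
    genes <- utils::read.delim(feat_file, header = FALSE)[[1]]
    cells <- utils::read.delim(bc_file, header = FALSE)[[1]]
    if (nrow(m) != length(genes))
      fr_stop("'%s' has %d rows but '%s' lists %d features",
              mtx_file, nrow(m), feat_file, length(genes))
    if (ncol(m) != length(cells))
      fr_stop("'%s' has %d columns but '%s' lists %d barcodes",
              mtx_file, ncol(m), bc_file, length(cells))
    values <- Matrix::t(methods::as(m, "CsparseMatrix"))
  } else if (format == "csv") {
    tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    cells <- as.character(tab[[1]])
    genes <- colnames(tab)[-1]
    values <- as.matrix(tab[, -1, drop = FALSE])
    mode(values) <- "double"
    rownames(values) <- cells
  } else {
    values <- rhdf5::h5read(path, "matrix")
    genes <- as.character(rhdf5::h5read(path, "gene_ids"))
    cells <- as.character(rhdf5::h5read(path, "cell_ids"))
    if (nrow(values) == length(genes) && ncol(values) == length(cells) &&
        length(genes) != length(cells)) {
      values <- t(values)                   # stored genes x cells; normalize
    } else if (!(nrow(values) == length(cells) && ncol(values) == length(genes))) {
      fr_stop("'%s': /matrix is %d x %d but gene_ids/cell_ids have lengths %d/%d",
              path, nrow(values), ncol(values), length(genes), length(cells))
    }
  }
  md <- read_metadata_table(metadata_path, as.character(cells))
  expression_data(values, md, gene_ids = as.character(genes),
                  cell_ids = as.character(cells), scale = scale)
}

write_one_matrix <- function(values, gene_ids, cell_ids, path, format) {
  if (format == "csv") {
    df <- data.frame(cell_id = cell_ids, as.matrix(values), check.names = FALSE)
    colnames(df) <- c("cell_id", gene_ids)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    sm <- methods::as(Matrix::t(Matrix::Matrix(values, sparse = TRUE)), "CsparseMatrix")
    Matrix::writeMM(sm, file.path(path, "matrix.mtx"))
    utils::write.table(data.frame(gene_ids), file.path(path, "features.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
    utils::write.table(data.frame(cell_ids), file.path(path, "barcodes.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  } else {
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(as.matrix(values), path, "matrix")
    rhdf5::h5write(gene_ids, path, "gene_ids")
    rhdf5::h5write(cell_ids, path, "cell_ids")
    rhdf5::h5closeAll()
  }
  invisible(NULL)
}

#' Write an (adjusted) expression matrix
#'
#' Writes the matrix in any supported format, optionally restricted to a gene
#' subset (e.g. the top highly variable genes) and optionally split into one
#' file per batch with a JSON manifest.
#'
#' @param data an [expression_data] object.
#' @param path output file (CSV/HDF5), directory (MTX), or directory when
#'   `by_batch = TRUE`.
#' @param format one of `"mtx"`, `"csv"`, `"hdf5"`.
#' @param genes optional character vector of gene IDs to keep, in the
#'   requested order.
#' @param by_batch write one file per batch label plus `manifest.json`.
#' @export
write_adjusted <- function(data, path, format = c("mtx", "csv", "hdf5"),
                           genes = NULL, by_batch = FALSE) {
  format <- match.arg(format)
  stopifnot(inherits(data, "expr_data"))
  gene_ids <- data$gene_ids
  values <- data$values
  if (!is.null(genes)) {
    unknown <- setdiff(genes, gene_ids)
    if (length(unknown))
      fr_stop("unknown gene ID(s): %s", paste(utils::head(unknown, 10), collapse = ", "))
    values <- values[, match(genes, gene_ids), drop = FALSE]
    gene_ids <- genes
  }
  if (!by_batch) {
    write_one_matrix(values, gene_ids, data$cell_ids, path, format)
    return(invisible(NULL))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  batches <- unique(data$metadata$batch)
  ext <- c(mtx = "", csv = ".csv", hdf5 = ".h5")[[format]]
  manifest <- list(format = format, n_genes = length(gene_ids), files = list())
  for (b in batches) {
    idx <- which(data$metadata$batch == b)
    fn <- file.path(path, paste0(gsub("[^A-Za-z0-9_.-]", "_", b), ext))
    write_one_matrix(values[idx, , drop = FALSE], gene_ids, data$cell_ids[idx], fn, format)
    manifest$files[[b]] <- list(path = basename(fn), n_cells = length(idx))
  }
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}
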