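## simulate module: negative-binomial multi-batch, multi-sample,
## two-condition count generator with planted batch effects and
## differential-state (DS) genes, plus an exact factor-model generator used
## as an oracle for the RUV-III estimators.

#' Simulation configuration
#'
#' Defines the synthetic study design. Defaults describe a compact benchmark
#' scenario: 2 batches, 2 conditions, 3 cell types, 4 samples per condition
#' with 100 cells each, 500 genes; batch effects are per-gene multiplicative
#' fold changes drawn log-normal(meanlog = log 2, sdlog = 0.43) with a random
#' sign per gene and batch (batch 1 is the reference); DS genes (a fraction
#' `ds_fraction` per cell type) receive a log2 fold change drawn
#' log-normal(meanlog = log(lfc_mu), sdlog = lfc_sd) applied to condition 2
#' with a random direction. Use `paper_scale_config()` for the published
#' 23-sample x 800-cell benchmark design.
#'
#' @param n_genes number of genes.
#' @param n_celltypes number of cell types.
#' @param n_samples_per_condition integer (same for both conditions) or
#'   length-2 vector of per-condition sample counts.
#' @param cells_per_sample cells per sample.
#' @param n_batches number of batches.
#' @param confound in a 2-batch design, the fraction of each condition's
#'   samples placed in its "own" batch (0.5 = balanced, 1 = fully
#'   confounded); ignored for `n_batches != 2`.
#' @param base_meanlog,base_sdlog log-normal parameters of the per-gene,
#'   per-cell-type base means.
#' @param dispersion_shape,dispersion_rate gamma parameters of the per-gene
#'   NB size (dispersion) parameter.
#' @param sample_effect_sd sd of the per-sample log-scale random shift.
#' @param batch_mu,batch_sd log-normal parameters of the batch fold change
#'   (defaults log(2) and 0.43).
#' @param ds_fraction fraction of DS genes per cell type (default 0.05).
#' @param lfc_mu typical DS log2 fold change (published grid 1.1 to 2.0).
#' @param lfc_sd sdlog of the DS log fold change (default 0.43).
#' @param seed integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 500, n_celltypes = 3,
                       n_samples_per_condition = 4, cells_per_sample = 100,
                       n_batches = 2, confound = 0.5,
                       base_meanlog = 0.5, base_sdlog = 1.2,
                       dispersion_shape = 2, dispersion_rate = 1,
                       sample_effect_sd = 0.1,
                       batch_mu = log(2), batch_sd = 0.43,
                       ds_fraction = 0.05, lfc_mu = 1.5, lfc_sd = 0.43,
                       seed = 1) {
  ns <- n_samples_per_condition
  if (length(ns) == 1) ns <- rep(ns, 2)
  stopifnot(length(ns) == 2, all(ns >= 1), ds_fraction >= 0, ds_fraction <= 1,
            batch_sd >= 0, lfc_sd >= 0, sample_effect_sd >= 0,
            confound >= 0.5, confound <= 1)
  structure(list(n_genes = n_genes, n_celltypes = n_celltypes,
                 n_samples_per_condition = ns,
                 cells_per_sample = cells_per_sample, n_batches = n_batches,
                 confound = confound, base_meanlog = base_meanlog,
                 base_sdlog = base_sdlog, dispersion_shape = dispersion_shape,
                 dispersion_rate = dispersion_rate,
                 sample_effect_sd = sample_effect_sd,
                 batch_mu = batch_mu, batch_sd = batch_sd,
                 ds_fraction = ds_fraction, lfc_mu = lfc_mu, lfc_sd = lfc_sd,
                 seed = seed),
            class = "sim_config")
}

#' Published-scale simulation design
#'
#' The benchmark design of the published simulation study: 23 samples (12 +
#' 11 across two conditions), 800 cells each (18,400 cells in total), with the
#' same batch-effect and DS parameters as [sim_config()].
#'
#' @param n_genes number of genes (default 1000).
#' @param ds_fraction 0.05 or 0.10 in the published grid.
#' @param lfc_mu DS fold-change location, 1.1 to 2.0 in the published grid.
#' @param ... further arguments to [sim_config()].
#' @export
paper_scale_config <- function(n_genes = 1000, ds_fraction = 0.05,
                               lfc_mu = 1.5, ...) {
  sim_config(n_genes = n_genes, n_celltypes = 4,
             n_samples_per_condition = c(12, 11), cells_per_sample = 800,
             ds_fraction = ds_fraction, lfc_mu = lfc_mu, ...)
}

## Deterministic sample-to-batch assignment. For 2 batches, condition j keeps
## round(confound * n_j) of its samples in batch j and sends the rest to the
## other batch; >2 batches are filled round-robin within condition.
assign_batches <- function(n_per_cond, n_batches, confound) {
  out <- list()
  for (j in seq_along(n_per_cond)) {
    n <- n_per_cond[j]
    if (n_batches == 2) {
      own <- if (j <= 2) j else 1L
      n_own <- round(confound * n)
      b <- c(rep(own, n_own), rep(3L - own, n - n_own))
    } else {
      b <- ((seq_len(n) - 1L + (j - 1L)) %% n_batches) + 1L
    }
    out[[j]] <- b
  }
  out
}

#' Simulate multi-batch, multi-condition single-cell counts
#'
#' Draws counts from a negative binomial with mean
#' `mu[g, t] * exp(eta_s) * FC_batch(g, b) * FC_ds(g, t, c)` and per-gene
#' dispersion, where `mu[g, t]` are per-gene/cell-type base means, `eta_s` a
#' per-sample random shift, `FC_batch` the planted multiplicative batch
#' effect and `FC_ds` the planted differential-state fold change (condition 2
#' only). Genes are conditionally independent. Cell types are near-equally
#' represented within each sample.
#'
#' @param config a [sim_config()].
#' @return list with `data` (an [expression_data] of counts, metadata columns
#'   `batch`, `sample`, `condition`, `cell_type`) and `truth` (a `sim_truth`:
#'   `ds` data.frame of planted DS genes with signed log2 fold changes,
#'   `batch_factors` gene x batch matrix, `samples` design table).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  G <- cf$n_genes; Tt <- cf$n_celltypes
  genes <- sprintf("gene%04d", seq_len(G))
  celltypes <- paste0("ct", seq_len(Tt))
  ns <- cf$n_samples_per_condition
  conditions <- c("cond1", "cond2")
  sample_cond <- rep(conditions, ns)
  sample_ids <- sprintf("s%02d", seq_along(sample_cond))
  batch_assign <- unlist(assign_batches(ns, cf$n_batches, cf$confound))
  sample_batch <- paste0("batch", batch_assign)

  seed0 <- stage_seed(cf$seed, "simulate")
  with_seed(seed0, {
    mu <- matrix(stats::rlnorm(G * Tt, cf$base_meanlog, cf$base_sdlog), G, Tt,
                 dimnames = list(genes, celltypes))
    theta <- stats::rgamma(G, shape = cf$dispersion_shape,
                           rate = cf$dispersion_rate) + 0.1
    eta <- stats::rnorm(length(sample_ids), 0, cf$sample_effect_sd)
    ## batch fold changes: batch 1 reference; per-gene-per-batch random sign
    bf <- matrix(1, G, cf$n_batches,
                 dimnames = list(genes, paste0("batch", seq_len(cf$n_batches))))
    if (cf$n_batches > 1) {
      L <- matrix(stats::rlnorm(G * (cf$n_batches - 1), cf$batch_mu, cf$batch_sd),
                  G, cf$n_batches - 1)
      S <- matrix(sample(c(-1, 1), G * (cf$n_batches - 1), replace = TRUE),
                  G, cf$n_batches - 1)
      bf[, -1] <- L^S
    }
    ## DS genes per cell type, applied to condition 2
    n_ds <- round(cf$ds_fraction * G)
    ds_fc <- matrix(1, G, Tt)                  # fold change on condition 2
    ds_rows <- list()
    for (t in seq_len(Tt)) {
      if (n_ds == 0) next
      sel <- sample.int(G, n_ds)
      lfc <- stats::rlnorm(n_ds, log(cf$lfc_mu), cf$lfc_sd)
      dir <- ifelse(stats::rbinom(n_ds, 1, 0.5) == 1, 1, -1)
      ds_fc[sel, t] <- 2^(dir * lfc)
      ds_rows[[t]] <- data.frame(cell_type = celltypes[t], gene = genes[sel],
                                 logFC = dir * lfc, direction = dir,
                                 stringsAsFactors = FALSE)
    }
    ds <- if (length(ds_rows)) do.call(rbind, ds_rows)
          else data.frame(cell_type = character(0), gene = character(0),
                          logFC = numeric(0), direction = integer(0))

    n_cells_total <- cf$cells_per_sample * length(sample_ids)
    counts <- matrix(0L, n_cells_total, G)
    meta <- vector("list", length(sample_ids))
    row0 <- 0L
    for (si in seq_along(sample_ids)) {
      nct <- cf$cells_per_sample
      ct_of_cell <- rep_len(seq_len(Tt), nct)  # near-equal representation
      b <- batch_assign[si]
      cidx <- which(sample_cond[si] == conditions)
      for (t in seq_len(Tt)) {
        cells_t <- sum(ct_of_cell == t)
        if (!cells_t) next
        mean_g <- mu[, t] * exp(eta[si]) * bf[, b]
        if (cidx == 2) mean_g <- mean_g * ds_fc[, t]
        block <- matrix(stats::rnbinom(cells_t * G,
                                       mu = rep(mean_g, each = cells_t),
                                       size = rep(theta, each = cells_t)),
                        cells_t, G)
        rows <- row0 + which(ct_of_cell == t)
        counts[rows, ] <- block
      }
      meta[[si]] <- data.frame(batch = sample_batch[si],
                               sample = sample_ids[si],
                               condition = sample_cond[si],
                               cell_type = celltypes[ct_of_cell],
                               stringsAsFactors = FALSE)
      row0 <- row0 + nct
    }
    metadata <- do.call(rbind, meta)
    cell_ids <- sprintf("cell%06d", seq_len(n_cells_total))
    data <- expression_data(counts, metadata, gene_ids = genes,
                            cell_ids = cell_ids, scale = "counts")
    truth <- structure(list(ds = ds, batch_factors = bf,
                            samples = data.frame(sample = sample_ids,
                                                 condition = sample_cond,
                                                 batch = sample_batch,
                                                 eta = eta,
                                                 stringsAsFactors = FALSE),
                            celltypes = celltypes,
                            ds_fraction = cf$ds_fraction),
                       class = "sim_truth")
    list(data = data, truth = truth)
  })
}

#' Generate exact factor-model data for oracle tests
#'
#' Draws every component of the model `Z = X beta + W alpha + eps` with a
#' replicate structure consistent with `X` (rows in one replicate set share
#' the same `X` row): the wanted design `X` is the one-hot encoding of the
#' replicate sets, `beta` has all-zero rows for a held-out fraction of genes
#' (the negative controls / SEGs), `alpha` has orthonormal rows, and `W` is
#' standard normal.
#'
#' @param C,G,k numbers of observations, genes and unwanted factors
#'   (`k < min(C, G)`).
#' @param n_sets number of replicate sets (default 5); observations are dealt
#'   round-robin, so every set is non-trivial.
#' @param seg_fraction fraction of genes with zero `beta` (default 0.3).
#' @param noise_sd sd of `eps` (0 gives the exact model).
#' @param beta_sd sd of the nonzero `beta` entries.
#' @param seed integer seed.
#' @return list with `Z`, `X`, `beta`, `W`, `alpha`, `M` (a
#'   `replicate_matrix`) and `seg_indices`.
#' @export
simulate_ruv_model <- function(C, G, k, n_sets = 5, seg_fraction = 0.3,
                               noise_sd = 0, beta_sd = 1, seed = 1) {
  if (k >= min(C, G)) fr_stop("k must be smaller than min(C, G)")
  if (n_sets > C) fr_stop("infeasible replicate structure: more sets than observations")
  with_seed(stage_seed(seed, "ruv-model"), {
    sets <- rep_len(seq_len(n_sets), C)
    M <- replicate_matrix(sets)
    X <- as.matrix(replicate_matrix(sets))     # one-hot, shared within set
    n_seg <- max(1, round(seg_fraction * G))
    seg_indices <- sort(sample.int(G, n_seg))
    beta <- matrix(stats::rnorm(n_sets * G, 0, beta_sd), n_sets, G)
    beta[, seg_indices] <- 0
    W <- matrix(stats::rnorm(C * k), C, k)
    A0 <- matrix(stats::rnorm(k * G), k, G)
    alpha <- t(svd(t(A0))$u[, seq_len(k), drop = FALSE])  # orthonormal rows
    eps <- if (noise_sd > 0) matrix(stats::rnorm(C * G, 0, noise_sd), C, G)
           else matrix(0, C, G)
    Z <- X %*% beta + W %*% alpha + eps
    list(Z = Z, X = X, beta = beta, W = W, alpha = alpha, M = M,
         seg_indices = seg_indices)
  })
}

#' Write a simulated dataset and its ground truth to disk
#'
#' @param sim output of [simulate_counts()].
#' @param dir output directory; the matrix goes in `dir` in the requested
#'   format, metadata to `metadata.tsv`, truth to `truth.tsv`.
#' @param format matrix format (see [write_adjusted()]).
#' @export
write_simulation <- function(sim, dir, format = c("mtx", "csv", "hdf5")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  target <- switch(format, mtx = dir, csv = file.path(dir, "counts.csv"),
                   hdf5 = file.path(dir, "counts.h5"))
  write_adjusted(sim$data, target, format = format)
  utils::write.table(cbind(cell_id = sim$data$cell_ids, sim$data$metadata),
                     file.path(dir, "metadata.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(sim$truth$ds, file.path(dir, "truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(NULL)
}
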