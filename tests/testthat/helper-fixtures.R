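## Shared fixtures, all generated in code.

## Minimal 3x2 count dataset with metadata.
tiny_expr <- function() {
  m <- matrix(c(0, 2, 4,
                2, 0, 1), nrow = 3, ncol = 2,
              dimnames = list(c("c1", "c2", "c3"), c("gA", "gB")))
  md <- data.frame(batch = c("b1", "b1", "b2"),
                   sample = c("s1", "s1", "s2"),
                   condition = c("x", "x", "y"))
  expression_data(m, md)
}

## Two (or more) Gaussian blobs; returns matrix and planted labels.
make_blobs <- function(n_per = 200, centers = 2, d = 10, sep = 10, sd = 1,
                       seed = 1) {
  set.seed(seed)
  mu <- matrix(0, centers, d)
  for (i in seq_len(centers)) mu[i, i] <- sep * sd
  x <- do.call(rbind, lapply(seq_len(centers), function(i) {
    matrix(rnorm(n_per * d, 0, sd), n_per, d) +
      matrix(mu[i, ], n_per, d, byrow = TRUE)
  }))
  list(x = x, labels = rep(seq_len(centers), each = n_per))
}

## Cells arranged as planted groups replicated across batches with additive
## per-batch shifts; group profiles are well separated.
planted_group_data <- function(n_batches = 3, n_groups = 4,
                               cells_per_group = 20, G = 30, sep = 8,
                               noise_sd = 1, batch_shift_sd = 2, seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(n_groups * G, 0, sep), n_groups, G)
  rows <- list(); md <- list()
  for (b in seq_len(n_batches)) {
    shift <- rnorm(G, 0, batch_shift_sd)
    for (g in seq_len(n_groups)) {
      m <- matrix(rnorm(cells_per_group * G, 0, noise_sd), cells_per_group, G) +
        matrix(centers[g, ] + shift, cells_per_group, G, byrow = TRUE)
      rows[[length(rows) + 1L]] <- m
      md[[length(md) + 1L]] <- data.frame(
        batch = rep(paste0("b", b), cells_per_group),
        sample = rep(paste0("b", b, "s1"), cells_per_group),
        group = rep(paste0("g", g), cells_per_group))
    }
  }
  m <- do.call(rbind, rows)
  md <- do.call(rbind, md)
  rownames(md) <- NULL
  data <- expression_data(m, md[, c("batch", "sample")], scale = "lognorm")
  grouping <- structure(list(labels = paste0(md$batch, "::", md$group),
                             source = "provided"), class = "cell_grouping")
  list(data = data, grouping = grouping, group = md$group, batch = md$batch)
}

## Dense replicate-residual projector, the independent oracle for
## residual_center: I - M (M'M)^{-1} M'.
dense_projector <- function(M) {
  M <- as.matrix(M)
  diag(nrow(M)) - M %*% solve(crossprod(M)) %*% t(M)
}

## Brute-force mutual-nearest-cluster components from centroids: all-pairs
## nearest search per batch pair plus transitive closure, independent of the
## package's graph code.
bf_mnc_components <- function(cent, batch, condition = NULL,
                              metric = "pearson") {
  n <- nrow(cent)
  dfun <- function(i, j) {
    if (metric == "euclidean") sqrt(sum((cent[i, ] - cent[j, ])^2))
    else 1 - cor(cent[i, ], cent[j, ])
  }
  ok <- function(i, j) {
    batch[i] != batch[j] &&
      (is.null(condition) || condition[i] == condition[j])
  }
  nearest <- function(i, in_batch) {
    cand <- which(batch == in_batch &
                    vapply(seq_len(n), function(j) ok(i, j), logical(1)))
    if (!length(cand)) return(NA_integer_)
    cand[which.min(vapply(cand, function(j) dfun(i, j), numeric(1)))]
  }
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (bj in setdiff(unique(batch), batch[i])) {
    j <- nearest(i, bj)
    if (!is.na(j) && identical(nearest(j, batch[i]), i)) {
      adj[i, j] <- TRUE; adj[j, i] <- TRUE
    }
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}
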