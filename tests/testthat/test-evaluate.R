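test_that("ARI is 1 on relabelings, ~0 on independent partitions", {
  p <- sample(1:4, 300, replace = TRUE)
  expect_equal(ari(p, p), 1.0)
  relab <- c(9, 12, 3, 7)[p]
  expect_equal(ari(p, relab), 1.0)
  set.seed(30)
  vals <- replicate(100, ari(sample(1:4, 1000, replace = TRUE),
                             sample(1:4, 1000, replace = TRUE)))
  expect_lt(abs(mean(vals)), 0.02)
  ## cross-check against an independent implementation
  set.seed(31)
  a <- sample(1:5, 200, replace = TRUE); b <- sample(1:3, 200, replace = TRUE)
  expect_equal(ari(a, b), mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  expect_error(ari(1:3, 1:4), "lengths")
})

test_that("silhouette behaves on separated, random and singleton labelings", {
  b <- make_blobs(n_per = 60, centers = 2, d = 4, sep = 20, seed = 32)
  expect_gt(asw(b$x, b$labels), 0.9)
  set.seed(33)
  one <- matrix(rnorm(200 * 3), 200, 3)
  vals <- replicate(20, asw(one, sample(1:2, 200, replace = TRUE)))
  expect_lt(abs(mean(vals)), 0.05)
  ## singleton label contributes 0, stays finite
  x <- rbind(matrix(rnorm(20), 10, 2), c(50, 50))
  s <- asw(x, c(rep(1, 10), 2))
  expect_true(is.finite(s))
  expect_error(asw(one, rep(1, 200)), "2 label")
})

test_that("PCA score isolates label-aligned variance", {
  set.seed(34)
  n <- 400
  batch <- rep(c(0, 1), each = n / 2)
  ## PC1 is an exact function of batch; remaining dims are iid noise
  m <- cbind(batch * 8 + rnorm(n, 0, 1e-3), matrix(rnorm(n * 9, 0, 2), n, 9))
  sc <- suppressWarnings(pca_score(m, batch))  # only 10 dims: PCs clamped
  emb <- suppressWarnings(pca_embed(m, d = 9))
  expect_equal(sc, emb$var_fraction[1], tolerance = 0.02)
  ## shuffled label drops to the chance level
  set.seed(35)
  sh <- replicate(20, suppressWarnings(pca_score(m, sample(batch))))
  expect_lt(mean(sh), 0.02)
  expect_error(pca_score(m, rep(1, n)), ">= 2 levels")
})

test_that("evaluation clustering recovers planted blobs and clamps PCs", {
  b <- make_blobs(n_per = 100, centers = 3, d = 25, sep = 12, seed = 36)
  md <- data.frame(batch = "b", sample = "s")[rep(1, 300), ]
  x <- expression_data(b$x, md, scale = "lognorm")
  part <- cluster_for_ari(x, seed = 1)
  expect_equal(ari(part, b$labels), 1.0)
  expect_warning(pca_embed(b$x[, 1:5], d = 20), "clamping")
})

test_that("the moderated test is calibrated and aggregation is exact", {
  ## aggregation of identical cells returns the common profile
  m <- matrix(rep(c(1, 2, 3, 4), each = 6), 6, 4)
  md <- data.frame(batch = "b", sample = rep(c("s1", "s2"), 3),
                   condition = rep(c("a", "b"), 3), cell_type = "T")
  md$condition <- ifelse(md$sample == "s1", "a", "b")
  x <- expression_data(m, md, scale = "lognorm")
  agg <- rowsum(as.matrix(x$values), md$sample) / as.vector(table(md$sample))
  expect_equal(unname(agg[1, ]), c(1, 2, 3, 4))

  ## a cell type with too few samples is skipped with a warning
  sim <- simulate_counts(sim_config(n_genes = 80, cells_per_sample = 20,
                                    n_samples_per_condition = 3, seed = 37))
  ln <- lognormalize(sim$data)
  ct <- ln$metadata$cell_type
  ct[ln$metadata$cell_type == "ct3" & ln$metadata$condition == "cond2"] <- "ct1"
  expect_warning(res <- ds_test(ln, celltype = ct), "skipped")
  expect_false("ct3" %in% res$cell_type)
  expect_true(all(c("logFC", "t", "p", "padj") %in% names(res)))
})

test_that("DS scoring implements the stated conventions", {
  truth <- structure(list(ds = data.frame(cell_type = "T",
                                          gene = c("g1", "g2"),
                                          logFC = c(1, -1),
                                          direction = c(1, -1))),
                     class = "sim_truth")
  calls <- data.frame(cell_type = "T", gene = paste0("g", 1:10),
                      padj = c(0.001, 0.004, rep(0.9, 8)))
  s <- score_ds(calls, truth)
  expect_equal(s$FDR, 0); expect_equal(s$TPR, 1); expect_equal(s$F1, 1)
  calls$padj <- 0.9
  s0 <- score_ds(calls, truth)
  expect_equal(s0$FDR, 0); expect_equal(s0$TPR, 0); expect_equal(s0$F1, 0)
  calls$padj <- c(rep(0.001, 4), rep(0.9, 6))   # g1,g2 TP + g3,g4 FP
  s2 <- score_ds(calls, truth)
  expect_equal(s2$FDR, 0.5); expect_equal(s2$TPR, 1)
  expect_equal(s2$F1, 2 * 2 / (2 * 2 + 2 + 0))
})

test_that("random calls at a fixed rate approach FDR = 1 - pi", {
  set.seed(38)
  G <- 1000; pi_ds <- 0.1
  truth <- structure(list(ds = data.frame(cell_type = "T",
                                          gene = paste0("g", 1:(G * pi_ds)),
                                          logFC = 1, direction = 1)),
                     class = "sim_truth")
  fdrs <- replicate(30, {
    called <- sample(G, 200)
    calls <- data.frame(cell_type = "T", gene = paste0("g", 1:G),
                        padj = ifelse(seq_len(G) %in% called, 0.01, 0.99))
    score_ds(calls, truth)$FDR
  })
  expect_equal(mean(fdrs), 1 - pi_ds, tolerance = 0.02)
})
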