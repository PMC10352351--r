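test_that("residual centering equals the dense projector", {
  set.seed(10)
  for (i in 1:10) {
    n <- sample(5:30, 1); G <- sample(3:12, 1)
    Z <- matrix(rnorm(n * G), n, G)
    M <- replicate_matrix(sample(1:4, n, replace = TRUE))
    expect_lt(max(abs(residual_center(Z, M) - dense_projector(as.matrix(M)) %*% Z)),
              1e-12)
  }
  ## two identical rows in a set -> both zero
  Z2 <- rbind(c(1, 2, 3), c(1, 2, 3), c(9, 9, 9))
  expect_equal(residual_center(Z2, c(1, 1, 2)),
               matrix(0, 3, 3), ignore_attr = TRUE)
  ## one global set -> column-mean centering
  set.seed(11)
  Z3 <- matrix(rnorm(40), 8, 5)
  expect_equal(residual_center(Z3, rep(1, 8)),
               sweep(Z3, 2, colMeans(Z3)), tolerance = 1e-12)
  ## idempotence of the projection
  M4 <- replicate_matrix(rep(1:3, length.out = 8))
  R1 <- residual_center(Z3, M4)
  expect_equal(residual_center(R1, M4), R1, tolerance = 1e-12)
})

test_that("alpha recovers a planted rank-1 residual direction", {
  set.seed(12)
  G <- 40; a <- rnorm(G); a <- a / sqrt(sum(a^2))
  sets <- rep(1:4, each = 5)
  means <- matrix(rnorm(4 * G), 4, G)
  coefs <- rnorm(20, 0, 3)
  Zb <- means[sets, ] + outer(coefs, a)
  est <- estimate_alpha(Zb, replicate_matrix(sets), k = 1)
  aln <- est$alpha[1, ] * sign(sum(est$alpha[1, ] * a))
  expect_lt(max(abs(aln - a)), 1e-8)
  ## orthonormal rows and fixed sign convention
  est3 <- estimate_alpha(Zb + matrix(rnorm(20 * G, 0, 0.1), 20, G),
                         replicate_matrix(sets), k = 3)
  expect_equal(est3$alpha %*% t(est3$alpha), diag(3), tolerance = 1e-8)
  for (i in 1:3) {
    j <- which.max(abs(est3$alpha[i, ]))
    expect_gt(est3$alpha[i, j], 0)
  }
})

test_that("k is clamped to the residual rank with a warning", {
  set.seed(13)
  G <- 20
  sets <- rep(1:3, each = 4)
  basis <- matrix(rnorm(2 * G), 2, G)
  Zb <- matrix(rnorm(12 * 2), 12, 2) %*% basis      # rank <= 2 + set means
  Zb <- residual_center(Zb, replicate_matrix(sets)) # exact rank <= 2
  expect_warning(est <- estimate_alpha(Zb, replicate_matrix(sets), k = 5),
                 "rank")
  expect_lte(est$k, 4)
  expect_equal(nrow(est$alpha), est$k)
  ## all-singleton sets: nothing to estimate from
  expect_error(estimate_alpha(matrix(rnorm(12), 4, 3), replicate_matrix(1:4),
                              k = 1), "no within-replicate variation")
})

test_that("W estimation solves the exact model and is linear", {
  set.seed(14)
  C <- 30; G <- 25; k <- 3
  A0 <- matrix(rnorm(k * G), k, G)
  alpha <- t(svd(t(A0))$u)
  W0 <- matrix(rnorm(C * k), C, k)
  Z <- W0 %*% alpha
  W <- estimate_W(Z, alpha, seq_len(G))
  expect_lt(max(abs(W - W0)), 1e-10)
  expect_equal(estimate_W(2 * Z, alpha, seq_len(G)), 2 * W, tolerance = 1e-10)
  ## degenerate: alpha zero on the SEG columns
  alpha0 <- alpha; alpha0[, 1:5] <- 0
  expect_warning(W0hat <- estimate_W(Z, alpha0, 1:5), "ill-conditioned")
  expect_true(all(is.finite(W0hat)))
  expect_error(estimate_W(Z, alpha, integer(0)), "empty SEG")
})

test_that("adjustment removes exactly what was planted and is idempotent", {
  for (seed in 1:10) {
    sim <- simulate_ruv_model(C = 60, G = 40, k = 3, n_sets = 5,
                              noise_sd = 0, seed = seed)
    est <- estimate_alpha(sim$Z, sim$M, k = 3)
    W <- estimate_W(sim$Z, est$alpha, sim$seg_indices)
    Zhat <- ruv_adjust(sim$Z, W, est$alpha)
    Xb <- sim$X %*% sim$beta
    expect_lt(norm(Zhat - Xb, "F") / norm(Xb, "F"), 1e-6)
  }
  ## identity at k = 0 and idempotence
  set.seed(15)
  Z <- matrix(rnorm(200), 20, 10)
  expect_identical(ruv_adjust(Z, NULL, NULL), Z)
  expect_identical(ruv_adjust(Z, matrix(0, 20, 0), matrix(0, 0, 10)), Z)
  sim <- simulate_ruv_model(C = 40, G = 30, k = 2, noise_sd = 0.05, seed = 3)
  est <- estimate_alpha(sim$Z, sim$M, k = 2)
  W1 <- estimate_W(sim$Z, est$alpha, sim$seg_indices)
  Z1 <- ruv_adjust(sim$Z, W1, est$alpha)
  W2 <- estimate_W(Z1, est$alpha, sim$seg_indices)
  Z2 <- ruv_adjust(Z1, W2, est$alpha)
  expect_lt(max(abs(Z2 - Z1)), 1e-8)
})

test_that("stability scores rank constant genes top and batch-specific genes low", {
  set.seed(16)
  n <- 60; G <- 30
  m <- matrix(abs(rnorm(n * G, 2, 1)), n, G)
  m[, 7] <- 3                                   # constant, nonzero everywhere
  batch <- rep(c("b1", "b2"), each = n / 2)
  m[batch == "b2", 19] <- 0                     # expressed in one batch only
  m[batch == "b1", 19] <- abs(rnorm(n / 2, 4, 2))
  md <- data.frame(batch = batch, sample = batch)
  x <- expression_data(m, md, scale = "lognorm")
  sc <- compute_seg_scores(x)
  expect_equal(which.max(sc), 7, ignore_attr = TRUE)
  expect_lt(rank(sc)[19], G / 2)
  ## permutation equivariance under cell shuffling
  ord <- sample(n)
  x2 <- expression_data(m[ord, ], md[ord, ], scale = "lognorm")
  expect_equal(compute_seg_scores(x2), sc, tolerance = 1e-12)
  ## selection honours lists, masks, and reports unmatched entries
  expect_warning(idx <- select_seg_indices(x, seg = c("gene3", "nope")),
                 "not found")
  expect_equal(x$gene_ids[idx], "gene3")
  idx2 <- select_seg_indices(x, zero_variance_mask = rep(FALSE, G))
  expect_true(7 %in% idx2)
})
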