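## 4 cohorts nested in 2 studies, with an extra study-level multiplicative
## effect planted on top of the per-cohort batch effects.
nested_sim <- function(seed, cells_per_sample = 50, n_genes = 300) {
  sim <- simulate_counts(sim_config(n_batches = 4, n_samples_per_condition = 4,
                                    cells_per_sample = cells_per_sample,
                                    n_genes = n_genes, seed = seed))
  d <- sim$data
  md <- d$metadata
  md$cohort <- md$batch
  md$study <- ifelse(md$batch %in% c("batch1", "batch2"), "s1", "s2")
  set.seed(seed + 5000)
  L <- rlnorm(ncol(d$values), log(2), 0.43) ^
    sample(c(-1, 1), ncol(d$values), replace = TRUE)
  v <- as.matrix(d$values)
  i2 <- md$study == "s2"
  v[i2, ] <- round(sweep(v[i2, , drop = FALSE], 2, L, "*"))
  md$batch <- md$study
  expression_data(v, md, gene_ids = d$gene_ids, cell_ids = d$cell_ids,
                  scale = "counts")
}

two_level_tree <- function(k_ruv = 10) {
  merge_tree(
    list(merge_collection(c("batch1", "batch2"), name = "s1",
                          batch_column = "cohort", k_ruv = k_ruv),
         merge_collection(c("batch3", "batch4"), name = "s2",
                          batch_column = "cohort", k_ruv = k_ruv)),
    list(merge_collection(c("s1", "s2"), name = "cross",
                          batch_column = "study", k_ruv = k_ruv)))
}

test_that("merge-tree configs parse from JSON and YAML with validation", {
  f <- system.file("extdata", "tree_rna.json", package = "fastruv")
  tr <- read_merge_tree(f)
  expect_s3_class(tr, "merge_tree")
  expect_length(tr$levels, 2)
  expect_equal(tr$levels[[1]][[1]]$k_ruv, 10)
  expect_equal(read_merge_tree(system.file("extdata", "tree_adt.json",
                                           package = "fastruv"))$levels[[2]][[1]]$k_ruv, 3)
  ## same tree via YAML
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("levels:",
               "  - - name: lv1", "      members: [b1, b2]",
               "      k_ruv: 4"), tmp)
  tr2 <- read_merge_tree(tmp)
  expect_equal(tr2$levels[[1]][[1]]$members, c("b1", "b2"))

  d <- nested_sim(1, cells_per_sample = 5, n_genes = 30)
  bad <- merge_tree(list(merge_collection(c("batch1", "ghost"),
                                          batch_column = "cohort")))
  expect_error(run_tree(d, bad, seed = 1), "unknown batch value")
  overlap <- merge_tree(list(merge_collection("batch1", batch_column = "cohort"),
                             merge_collection(c("batch1", "batch2"),
                                              batch_column = "cohort")))
  expect_error(run_tree(d, overlap, seed = 1), "overlap")
})

test_that("degenerate trees pass through", {
  sim <- simulate_counts(sim_config(n_genes = 60, cells_per_sample = 20,
                                    n_samples_per_condition = 2, seed = 2))
  ln <- lognormalize(sim$data)
  ## empty tree: input unchanged with warning
  expect_warning(res <- run_tree(ln, merge_tree(), seed = 1), "empty")
  expect_identical(res$data$values, ln$values)
  ## single-batch collection: warning + exact pass-through
  one <- subset_idx <- which(ln$metadata$batch == "batch1")
  sub <- expression_data(as.matrix(ln$values)[one, ],
                         ln$metadata[one, c("batch", "sample", "condition")],
                         gene_ids = ln$gene_ids, cell_ids = ln$cell_ids[one],
                         scale = "lognorm")
  tr <- merge_tree(list(merge_collection("batch1")))
  expect_warning(res1 <- run_tree(sub, tr, seed = 1), "single batch")
  expect_identical(res1$data$values, sub$values)
})

test_that("a one-level one-collection tree reproduces the flat run bit-exactly", {
  sim <- simulate_counts(sim_config(n_genes = 120, cells_per_sample = 40,
                                    n_samples_per_condition = 2, seed = 3))
  flat <- fastruv(sim$data, seed = 11, k_ruv = 5)
  tr <- merge_tree(list(merge_collection(unique(sim$data$metadata$batch),
                                         name = "everything")))
  tree_fit <- fastruv(sim$data, tree = tr, seed = 11, k_ruv = 5)
  expect_identical(flat$adjusted$values, tree_fit$adjusted$values)
})

test_that("levels preserve order and feed forward deterministically", {
  d <- nested_sim(4)
  tr <- two_level_tree()
  f1 <- fastruv(d, tree = tr, seed = 21, k_ruv = 10)
  f2 <- fastruv(d, tree = tr, seed = 21, k_ruv = 10)
  expect_identical(f1$adjusted$values, f2$adjusted$values)
  expect_identical(f1$adjusted$cell_ids, d$cell_ids)
  expect_identical(f1$adjusted$gene_ids, d$gene_ids)
  expect_equal(nrow(f1$diagnostics), 3)
  expect_equal(f1$diagnostics$level, c(1, 1, 2))
  ## per-level diagnostics carry the replicate structure log
  expect_true(all(f1$diagnostics$n_sets[!f1$diagnostics$skipped] >= 1))
})

test_that("hierarchical merging beats the flat coarse-label run on nested structure", {
  wins <- 0
  for (seed in 1:10) {
    d <- nested_sim(seed)
    flat <- fastruv(d, seed = seed, k_ruv = 10)       # batch label = study
    hier <- fastruv(d, tree = two_level_tree(), seed = seed)
    a_flat <- asw(pca_embed(flat$adjusted)$scores, d$metadata$cohort)
    a_hier <- asw(pca_embed(hier$adjusted)$scores, d$metadata$cohort)
    wins <- wins + (a_hier < a_flat)
  }
  expect_gte(wins, 8)
})
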