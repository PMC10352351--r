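## Planted T-like / B-like populations in two batches.
two_pop_pb <- function(seed = 1, conditions = FALSE) {
  p <- planted_group_data(n_batches = 2, n_groups = 2, cells_per_group = 12,
                          G = 20, seed = seed)
  md <- p$data$metadata
  if (conditions) md$condition <- rep_len(c("healthy", "severe"),
                                          nrow(md))
  construct_pseudobulk(p$data$values, p$grouping, md, k = 4, seed = seed)
}

test_that("planted populations pair up as mutual nearest clusters", {
  pb <- two_pop_pb(1)
  g <- build_mnc_graph(pb, per_condition = FALSE)
  expect_equal(nrow(g$edges), 2)
  pair <- function(e) paste(sort(c(sub("@.*", "", e["from"]),
                                   sub("@.*", "", e["to"]))), collapse = "|")
  got <- sort(apply(g$edges, 1, pair))
  expect_identical(got, c("b1::g1|b2::g1", "b1::g2|b2::g2"))
})

test_that("a single batch yields an empty edge set with a warning", {
  p <- planted_group_data(n_batches = 1, n_groups = 2, seed = 2)
  pb <- construct_pseudobulk(p$data$values, p$grouping, p$data$metadata,
                             k = 4, seed = 2)
  expect_warning(g <- build_mnc_graph(pb, per_condition = FALSE),
                 "fewer than 2 batches")
  expect_equal(nrow(g$edges), 0)
  ## disconnected graph: one replicate set per node
  M <- replicate_sets_from_graph(g, pb)
  expect_equal(M$n_sets, nrow(g$nodes))
})

test_that("condition-aware mode never links conditions", {
  pb <- two_pop_pb(3, conditions = TRUE)
  g <- build_mnc_graph(pb, per_condition = TRUE)
  expect_gt(nrow(g$edges), 0)
  cond_of <- function(id) sub("^.*@", "", id)
  expect_true(all(cond_of(g$edges$from) == cond_of(g$edges$to)))
  M <- replicate_sets_from_graph(g, pb)
  for (s in unique(M$sets))
    expect_equal(length(unique(pb$rows$condition[M$sets == s])), 1)
})

test_that("replicate matrix has the partition structure", {
  pb <- two_pop_pb(4)
  g <- build_mnc_graph(pb, per_condition = FALSE)
  M <- replicate_sets_from_graph(g, pb)
  Mm <- as.matrix(M)
  expect_true(all(rowSums(Mm) == 1))
  expect_true(all(colSums(Mm) >= 1))
  expect_equal(qr(Mm)$rank, M$n_sets)
  ## the planted component {b1::g1, b2::g1} pools all its pseudo-bulk rows
  comp_sets <- unique(M$sets[pb$rows$group %in% c("b1::g1", "b2::g1")])
  expect_equal(length(comp_sets), 1)
  expect_equal(sum(M$sets == comp_sets), sum(pb$rows$group %in%
                                               c("b1::g1", "b2::g1")))
})

test_that("identity case: one row per node, no edges -> R_M Z = 0", {
  set.seed(5)
  m <- matrix(rnorm(60), 6, 10)
  md <- data.frame(batch = paste0("b", 1:6), sample = paste0("s", 1:6),
                   condition = "c")
  grouping <- structure(list(labels = paste0(md$batch, "::g", 1:6),
                             source = "provided"), class = "cell_grouping")
  pb <- construct_pseudobulk(m, grouping, md, k = 30, seed = 1)
  g <- build_mnc_graph(pb, per_condition = FALSE)
  g$edges <- g$edges[0, ]                      # force full disconnection
  M <- replicate_sets_from_graph(g, pb)
  expect_equal(as.matrix(M), diag(6), ignore_attr = TRUE)
  expect_equal(max(abs(residual_center(pb$values, M))), 0)
})

test_that("chained components merge transitively and batch order is immaterial", {
  p <- planted_group_data(n_batches = 3, n_groups = 2, cells_per_group = 10,
                          G = 20, seed = 6)
  pb <- construct_pseudobulk(p$data$values, p$grouping, p$data$metadata,
                             k = 3, seed = 6)
  g <- build_mnc_graph(pb, per_condition = FALSE)
  M <- replicate_sets_from_graph(g, pb)
  ## each planted group should form one component spanning all 3 batches
  for (gr in c("g1", "g2")) {
    sets <- unique(M$sets[grepl(paste0("::", gr, "@"), pb$rows$node_id)])
    expect_equal(length(sets), 1)
  }
  ## permuting cell (and hence batch) order preserves component structure
  ord <- rev(seq_len(nrow(p$data$values)))
  md_r <- p$data$metadata[ord, ]
  gr_r <- structure(list(labels = p$grouping$labels[ord], source = "provided"),
                    class = "cell_grouping")
  pb_r <- construct_pseudobulk(p$data$values[ord, ], gr_r, md_r, k = 3,
                               seed = 6)
  M_r <- replicate_sets_from_graph(build_mnc_graph(pb_r, per_condition = FALSE),
                                   pb_r)
  expect_equal(M_r$n_sets, M$n_sets)
})

test_that("components agree with the brute-force oracle on planted structure", {
  for (seed in 1:3) {
    p <- planted_group_data(n_batches = 3, n_groups = 4, cells_per_group = 8,
                            G = 25, seed = seed)
    pb <- construct_pseudobulk(p$data$values, p$grouping, p$data$metadata,
                               k = 4, seed = seed)
    g <- build_mnc_graph(pb, per_condition = FALSE)
    M <- replicate_sets_from_graph(g, pb)
    comp_oracle <- bf_mnc_components(g$centroids, g$nodes$batch)
    node_set <- M$node_component[g$nodes$node_id]
    expect_equal(ari(comp_oracle, node_set), 1.0)
  }
})

test_that("replicate assignments export as a TSV audit trail", {
  pb <- two_pop_pb(7)
  g <- build_mnc_graph(pb, per_condition = FALSE)
  M <- replicate_sets_from_graph(g, pb)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_replicates(M, pb, tmp)
  tab <- read.delim(tmp)
  expect_equal(nrow(tab), nrow(pb$values))
  expect_true("replicate_set" %in% names(tab))
})
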