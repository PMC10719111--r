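test_that("variable-gene selection matches the binomial detection model", {
  # bimodal gene: high in half the cells, absent elsewhere
  set.seed(40)
  n <- 400
  m <- matrix(rpois(n * 20, 5), n, 20)
  m[, 1] <- 0
  m[seq_len(n / 2), 1] <- rpois(n / 2, 10)
  colnames(m) <- paste0("g", 1:20)
  sel <- select_variable_genes(m)
  expect_true("g1" %in% sel)
  # direct arithmetic oracle for the deficit of every gene
  depth <- rowSums(m)
  p <- colSums(m) / sum(m)
  expected <- colMeans(1 - exp(-outer(depth, p)))
  observed <- colMeans(m > 0)
  expect_setequal(sel, colnames(m)[observed <= expected - 0.05])
  # homogeneous Poisson genes are not selected
  expect_false(any(paste0("g", 2:20) %in% sel))
  # an all-zero gene has deficit 0
  m0 <- cbind(m, zz = 0L)
  expect_false("zz" %in% select_variable_genes(m0))
})

test_that("SNN weights equal brute-force Jaccard over kNN sets", {
  set.seed(41)
  x <- rbind(matrix(rnorm(15 * 3, 0), 15, 3), matrix(rnorm(15 * 3, 8), 15, 3))
  nn <- knn_indices(x, 5, "euclidean")
  g <- snn_graph(nn)
  el <- igraph::as_edgelist(g)
  w <- igraph::E(g)$weight
  # oracle: Jaccard from the neighbour sets directly
  for (e in seq_len(nrow(el))) {
    A <- nn[el[e, 1], ]; B <- nn[el[e, 2], ]
    expect_equal(w[e], length(intersect(A, B)) / length(union(A, B)))
  }
  # all intra-blob weights exceed all inter-blob weights
  blob <- rep(1:2, each = 15)
  intra <- w[blob[el[, 1]] == blob[el[, 2]]]
  inter <- w[blob[el[, 1]] != blob[el[, 2]]]
  expect_true(length(inter) == 0 || min(intra) > max(inter))
  # identical kNN sets give weight 1; disjoint sets give no edge
  nn2 <- rbind(c(3, 4), c(3, 4), c(1, 2), c(1, 2))
  g2 <- snn_graph(nn2)
  m2 <- igraph::as_adjacency_matrix(g2, attr = "weight", sparse = FALSE)
  expect_equal(m2[1, 2], 1)
  expect_equal(m2[3, 4], 1)
})

test_that("the Leiden sweep splits structure and stops on homogeneity", {
  # two 50-cliques joined by one edge: split into the cliques
  g <- igraph::make_full_graph(50) + igraph::make_full_graph(50)
  g <- igraph::add_edges(g, c(1, 51))
  igraph::E(g)$weight <- 1
  sw <- leiden_sweep(g, seed = 42)
  expect_equal(sw$status, "split")
  expect_equal(length(unique(sw$membership)), 2)
  expect_true(all(sw$membership[1:50] == sw$membership[1]))
  expect_true(all(sw$membership[51:100] == sw$membership[51]))
  # a single clique never produces a valid partition
  g1 <- igraph::make_full_graph(100)
  igraph::E(g1)$weight <- 1
  expect_equal(leiden_sweep(g1, seed = 43)$status, "no_split")
  # a multi-component graph stops the sweep immediately
  g2 <- igraph::make_full_graph(30) + igraph::make_full_graph(30)
  igraph::E(g2)$weight <- 1
  expect_equal(leiden_sweep(g2, seed = 44)$status, "disconnected")
  expect_error(leiden_sweep(igraph::make_empty_graph(0)), "empty")
})

test_that("marker test applies the three discrete criteria", {
  set.seed(45)
  n <- 120
  lab <- rep(1:2, each = n / 2)
  m <- matrix(rpois(n * 30, 3), n, 30)
  colnames(m) <- paste0("g", 1:30)
  # 4 genes up in cluster 1 (60% vs 2%), 4 genes up in cluster 2
  for (j in 1:4) m[, j] <- ifelse(lab == 1, rbinom(n, 1, 0.6), rbinom(n, 1, 0.02)) * rpois(n, 6)
  for (j in 5:8) m[, j] <- ifelse(lab == 2, rbinom(n, 1, 0.6), rbinom(n, 1, 0.02)) * rpois(n, 6)
  res <- test_cluster_markers(m, lab)
  expect_equal(res$decision, "keep")
  expect_gte(res$pair_counts["1", "2"], 3)
  expect_gte(res$pair_counts["2", "1"], 3)
  # identical clusters merge
  m2 <- matrix(rpois(n * 30, 3), n, 30); colnames(m2) <- paste0("g", 1:30)
  expect_equal(test_cluster_markers(m2, lab)$decision, "merge")
  # a 25% vs 15% gene fails the strict low-side rule
  m3 <- m2
  m3[, 1] <- ifelse(lab == 1, rbinom(n, 1, 0.25), rbinom(n, 1, 0.15)) * rpois(n, 50)
  res3 <- test_cluster_markers(m3, lab)
  expect_false("g1" %in% res3$pairs$gene)
  # a singleton cluster merges automatically
  expect_equal(test_cluster_markers(m, c(rep(1, n - 1), 2))$decision, "merge")
})

test_that("marker pass counts equal the brute-force reimplementation", {
  set.seed(46)
  for (rep_i in 1:8) {
    n <- 60; ngene <- 20
    lab <- sample(1:2, n, replace = TRUE)
    if (min(table(lab)) < 5) next
    m <- matrix(rpois(n * ngene, 2), n, ngene)
    colnames(m) <- paste0("g", seq_len(ngene))
    nmk <- sample(0:4, 1)
    for (j in seq_len(nmk))
      m[, j] <- ifelse(lab == 1, rbinom(n, 1, runif(1, 0.3, 0.9)),
                       rbinom(n, 1, runif(1, 0, 0.15))) * rpois(n, 8)
    got <- test_cluster_markers(m, lab)
    want <- oracle_marker_pairs(m, lab)
    expect_equal(unname(got$pair_counts), unname(want))
  }
})

test_that("recursive clustering terminates on homogeneous data and partitions cells", {
  tr <- build_ground_truth(2, 150, doublet_rate = 0, seed = 47)
  # a single type: one leaf, reason recorded
  cells <- simulate_cells(tr, 300, 3000, seed = 48)
  one <- subset_cells(cells, which(cells$cell_meta$truth_type == "T01"))
  ct <- iterative_cluster(one, seed = 49)
  expect_length(ct$leaves, 1)
  expect_true(ct$nodes[["root"]]$reason %in%
                c("no_split", "disconnected_trivial", "no_markers_merged"))
  # partition property on structured data
  tr2 <- build_ground_truth(4, 200, seed = 50)
  cells2 <- simulate_cells(tr2, 1200, 5000, seed = 51)
  ct2 <- iterative_cluster(cells2, seed = 52)
  in_leaf <- !is.na(ct2$assignments)
  expect_true(all(xor(in_leaf, seq_along(ct2$assignments) %in% ct2$discarded)))
  expect_lt(length(ct2$discarded) / 1200, 0.05)
  # determinism
  ct3 <- iterative_cluster(cells2, seed = 52)
  expect_identical(ct2$assignments, ct3$assignments)
  # monotonicity: demanding 5 markers never yields more leaves than 3
  ct5 <- iterative_cluster(cells2, n_required = 5, seed = 52)
  expect_lte(length(ct5$leaves), length(ct2$leaves))
})
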