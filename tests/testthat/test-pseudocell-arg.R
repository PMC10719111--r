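test_that("the pseudocell size rule reproduces its closed form", {
  expect_equal(pseudocell_size(10000), 200)
  expect_equal(pseudocell_size(500), 20)
  expect_equal(pseudocell_size(2500), 50)
  expect_equal(pseudocell_size(1), 20)
  expect_equal(pseudocell_size(1e7), 200)
})

test_that("pseudocell construction partitions types and conserves counts", {
  tr <- build_ground_truth(3, 150, doublet_rate = 0, seed = 90)
  cells <- simulate_cells(tr, 400, 3000, seed = 91)
  lab <- cells$cell_meta$truth_type
  # a 40-cell type (s = 20) splits into 2 pseudocells; a 15-cell type stays whole
  idx <- c(which(lab == "T01")[1:40], which(lab == "T02")[1:15])
  sub <- subset_cells(cells, idx)
  ps <- build_pseudocells(sub, lab[idx], seed = 92)
  expect_equal(sum(ps$meta$type == "T01"), 2)
  expect_equal(sum(ps$meta$type == "T02"), 1)
  # every cell in exactly one pseudocell; never across types
  expect_false(any(is.na(ps$membership)))
  expect_true(all(startsWith(ps$membership, lab[idx])))
  # aggregation conserves counts per gene exactly
  expect_equal(colSums(ps$counts), Matrix::colSums(sub$counts))
  expect_equal(sum(ps$counts), sum(sub$counts))
})

test_that("pseudocells are pure for well-separated subpopulations", {
  # one labelled "type" hiding two populations with disjoint strong genes
  set.seed(93)
  n <- 120; g <- 60
  m <- matrix(rpois(n * g, 1), n, g)
  m[1:60, 1:10] <- rpois(60 * 10, 30)
  m[61:120, 11:20] <- rpois(60 * 10, 30)
  colnames(m) <- paste0("g", seq_len(g))
  cells <- profile_from_matrix(m)
  ps <- build_pseudocells(cells, rep("mix", n), seed = 94)
  truth_sub <- rep(c("p1", "p2"), each = 60)
  purity <- vapply(ps$meta$pseudocell, function(p) {
    mem <- which(ps$membership == p)
    max(table(truth_sub[mem])) / length(mem)
  }, numeric(1))
  expect_true(all(purity >= 0.9))
})

test_that("pseudocell normalization standardizes, flags, and preserves ranks", {
  set.seed(95)
  m <- matrix(rpois(20 * 40, 10), 20, 40)
  m[, 40] <- 7L  # a constant gene after CPM differs by depth; make depth equal
  colnames(m) <- paste0("g", 1:40)
  rownames(m) <- paste0("p", 1:20)
  norm <- normalize_pseudocells(m)
  z <- norm$normalized
  expect_true(all(abs(colMeans(z)) < 1e-8))
  sds <- apply(z, 2, stats::sd)
  expect_true(all(abs(sds[sds > 0] - 1) < 1e-6))
  # two identical pseudocells normalize to identical rows
  m2 <- rbind(m, m[1, ], m[1, ])
  rownames(m2) <- c(rownames(m), "dupA", "dupB")
  z2 <- normalize_pseudocells(m2)$normalized
  expect_equal(z2["dupA", ], z2["dupB", ])
  # permutation equivariance over pseudocells
  perm <- sample(nrow(m))
  z3 <- normalize_pseudocells(m[perm, ])$normalized
  expect_equal(z3, z[perm, ])
  # quantile normalization preserves within-pseudocell ranking
  qn <- norm$quantile_normalized
  for (i in seq_len(nrow(m))) {
    expect_equal(rank(qn[i, ], ties.method = "average"),
                 rank(m[i, ] / sum(m[i, ]), ties.method = "average"))
  }
  expect_error(normalize_pseudocells(rbind(m, 0)), "zero-count")
  expect_error(normalize_pseudocells(m[1, , drop = FALSE]), "at least 2")
})

test_that("ARG candidates satisfy the three-criteria conjunction", {
  z <- planted_arg_matrix(200, 8, 150, r = 0.8, seed = 96)
  tab <- arg_candidates(z, rep("grp", nrow(z)))
  cand <- attr(tab, "candidates")
  expect_true(all(paste0("Mod", 1:8) %in% cand))
  # the anchor is never its own candidate
  expect_false("Fos" %in% cand)
  expect_false("Fos" %in% tab$gene)
  # every candidate row satisfies the conjunction it claims
  cr <- tab[tab$candidate, ]
  expect_true(all(cr$r >= 0.3 & cr$r_quantile >= 0.995 & cr$p_holm < 0.05))
  # r below 0.3 is never a candidate regardless of p
  expect_false(any(tab$candidate & tab$r < 0.3))
  # groups below the floor are skipped with a warning
  expect_warning(arg_candidates(z[1:5, ], rep("tiny", 5)), "fewer than")
})

test_that("Holm adjustment inside the ARG table equals the step-down oracle", {
  set.seed(97)
  for (i in 1:20) {
    p <- runif(sample(3:30, 1))
    expect_equal(stats::p.adjust(p, method = "holm"), oracle_holm(p))
  }
  # the table's adjusted values are the Holm step-down of its raw t-test p
  z <- planted_arg_matrix(80, 3, 30, r = 0.6, seed = 98)
  tab <- arg_candidates(z, rep("grp", nrow(z)))
  n <- nrow(z)
  r <- tab$r
  praw <- 2 * stats::pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2)
  expect_equal(tab$p_holm, oracle_holm(praw), tolerance = 1e-12)
})

test_that("the ARG network prunes at 1.3 and calls cores above degree 18", {
  tab <- data.frame(
    gene = rep(c("gA", "gB", "gC"), times = c(28, 28, 2)),
    group = c(paste0("r", 1:28), paste0("r", 1:28), "r1", "r2"),
    r = c(rep(0.5, 19), rep(0.31, 9),      # gA: 28 kept edges
          rep(0.30, 19), rep(0.25, 9),     # gB: 19 kept (0.30 survives)
          0.29, 0.2),                      # gC: all pruned
    p_holm = 0.001, r_quantile = 1, candidate = TRUE,
    stringsAsFactors = FALSE)
  attr(tab, "candidates") <- c("gA", "gB", "gC")
  class(tab) <- c("arg_table", "data.frame")
  net <- arg_network(tab)
  expect_equal(unname(net$degree[c("gA", "gB", "gC")]), c(28L, 19L, 0L))
  expect_setequal(net$core, c("gA", "gB"))
  expect_true(all(net$edges$e >= 1.3))
})

test_that("ARG clustering separates orthogonal modules and keeps duplicates together", {
  groups <- paste0("r", 1:10)
  mk_rows <- function(gene, rs) data.frame(gene = gene, group = groups, r = rs,
                                           p_holm = 0.001, r_quantile = 1,
                                           candidate = TRUE,
                                           stringsAsFactors = FALSE)
  tab <- rbind(mk_rows("a1", c(rep(0.8, 5), rep(0, 5))),
               mk_rows("a2", c(rep(0.7, 5), rep(0, 5))),
               mk_rows("a3", c(rep(0.8, 5), rep(0, 5))),   # duplicate of a1
               mk_rows("b1", c(rep(0, 5), rep(0.8, 5))),
               mk_rows("b2", c(rep(0, 5), rep(0.7, 5))))
  attr(tab, "candidates") <- c("a1", "a2", "a3", "b1", "b2")
  class(tab) <- c("arg_table", "data.frame")
  cl <- arg_clusters(tab, k = 2)
  expect_equal(cl[["a1"]], cl[["a2"]])
  expect_equal(cl[["a1"]], cl[["a3"]])
  expect_equal(cl[["b1"]], cl[["b2"]])
  expect_false(cl[["a1"]] == cl[["b1"]])
  # k = number of genes gives singletons
  expect_equal(sort(unname(arg_clusters(tab, k = 5))), 1:5)
  expect_error(arg_clusters(tab, k = 6), "exceeds")
})

test_that("gene-set overlap reports cross-product odds ratios with Bonferroni", {
  universe <- paste0("g", 1:100)
  # (5, 5, 5, 85)
  res <- geneset_overlap(paste0("g", 1:10), paste0("g", 6:15), universe)
  expect_equal(res$odds_ratio, 17.0)
  expect_equal(res$overlap, 5)
  # identity overlap: hypergeometric-tail oracle
  res2 <- geneset_overlap(paste0("g", 1:10), paste0("g", 1:10), universe)
  p_want <- stats::dhyper(10, 10, 90, 10)
  expect_lt(res2$p, 1e-10)
  expect_equal(res2$p, p_want, tolerance = 1e-12)
  # disjoint sets covering the universe: no enrichment evidence
  res3 <- geneset_overlap(paste0("g", 1:50), paste0("g", 51:100), universe)
  expect_lt(res3$odds_ratio, 1)
  expect_equal(res3$p, 1)
  # Bonferroni multiplies and caps
  res4 <- geneset_overlap(paste0("g", 1:10), paste0("g", 6:15), universe,
                          n_comparisons = 1e6)
  expect_equal(res4$p, 1)
  expect_error(geneset_overlap("g1", "g1", character(0)), "empty")
})
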