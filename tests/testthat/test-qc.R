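test_that("basic filter applies the strict UMI and mito thresholds", {
  # 6 genes: one mitochondrial, five ordinary
  m <- rbind(
    c(0, 100, 100, 100, 100, 99),   # 499 UMIs -> low_umi
    c(5, 100, 100, 100, 100, 95),   # 500 UMIs, 1.0% mito -> retained
    c(6, 100, 100, 100, 100, 94),   # 1.2% mito -> high_mito
    c(0, 200, 100, 100, 100, 100)   # retained
  )
  colnames(m) <- c("mt-1", paste0("g", 1:5))
  cells <- profile_from_matrix(m)
  rep <- basic_filter(cells)
  expect_setequal(rep$retained, c("c002", "c004"))
  expect_equal(rep$removed$reason[rep$removed$cell_id == "c001"], "low_umi")
  expect_equal(rep$removed$reason[rep$removed$cell_id == "c003"], "high_mito")
  expect_error(basic_filter(cells, mito_regex = "^nope"), "matches no genes")
})

test_that("basic filter removes exactly the planted low-depth cells and is idempotent", {
  tr <- build_ground_truth(3, 200, doublet_rate = 0, seed = 20)
  cells <- simulate_cells(tr, 400, 2000, seed = 21)
  # force 10% of cells below depth 400 by truncating their counts
  m <- as.matrix(cells$counts)
  low <- seq_len(40)
  for (i in low) {
    v <- rep(colnames(m), m[i, ])
    keep <- table(factor(sample(v, 350), levels = colnames(m)))
    m[i, ] <- as.integer(keep)
  }
  forced <- profile_from_matrix(m)
  rep <- basic_filter(forced)
  removed_low <- rep$removed$cell_id[rep$removed$reason == "low_umi"]
  expect_setequal(removed_low, rownames(m)[low])
  # idempotence: filtering the retained set removes nothing
  rep2 <- basic_filter(subset_cells(forced, rep$retained))
  expect_equal(nrow(rep2$removed), 0)
  # monotonicity: raising the cutoff never retains a removed cell
  rep3 <- basic_filter(forced, min_umis = 800)
  expect_true(all(rep$removed$cell_id %in%
                    c(rep3$removed$cell_id)))
})

test_that("doublet clusters are flagged by cross-class co-expression", {
  tr <- build_ground_truth(2, 100, doublet_rate = 0, seed = 22)
  a <- simulate_cells(tr, 100, 3000, seed = 23)
  mk <- tr$marker_table
  gA <- mk$gene[mk$type == "T01"][1]; gB <- mk$gene[mk$type == "T02"][1]
  # cluster 3 is a synthetic mixture co-expressing both markers
  m <- as.matrix(a$counts)
  mix <- (m[a$cell_meta$truth_type == "T01", ][1:20, ] +
            m[a$cell_meta$truth_type == "T02", ][1:20, ])
  all_m <- rbind(m, mix)
  rownames(all_m) <- sprintf("c%03d", seq_len(nrow(all_m)))
  cells <- profile_from_matrix(all_m)
  labels <- c(a$cell_meta$truth_type, rep("DBL", 20))
  flagged <- flag_doublet_clusters(labels, cells, cbind(gA, gB))
  expect_identical(flagged, "DBL")
  expect_length(flag_doublet_clusters(labels, cells,
                                      matrix(character(0), 0, 2)), 0)
  expect_error(flag_doublet_clusters(labels, cells, cbind("absent", gB)),
               "absent")
})

test_that("quality network removes planted stressed cells and tiny clusters", {
  set.seed(24)
  n <- 1000
  mets <- data.frame(
    pct_oxphos = rbeta(n, 2, 60), pct_mito = rbeta(n, 1, 120),
    pct_ribo = rbeta(n, 2, 40), pct_ieg = rbeta(n, 1, 100),
    pct_top50 = rbeta(n, 10, 10), pct_lncRNA = rbeta(n, 1, 50),
    log2_genes = rnorm(n, 10, 0.3), log2_umis = rnorm(n, 12, 0.3))
  # 5% stressed population: all three flagged families near the top
  stressed <- seq_len(50)
  mets$pct_oxphos[stressed] <- rbeta(50, 60, 10)
  mets$pct_mito[stressed] <- rbeta(50, 60, 10)
  mets$pct_ribo[stressed] <- rbeta(50, 60, 10)
  cells <- profile_from_matrix(matrix(5L, n, 30))
  rep <- quality_network_qc(cells, mets, rep("neuron", n), seed = 25)
  removed_q <- rep$removed$cell_id[rep$removed$reason == "quality_cluster"]
  expect_gte(length(intersect(removed_q, rownames(cells$counts)[stressed])), 45)
  expect_lte(length(setdiff(removed_q, rownames(cells$counts)[stressed])), 25)

  # homogeneous metrics: the three-feature rule removes nothing
  set.seed(26)
  mets2 <- as.data.frame(lapply(mets, function(v) rnorm(n, mean(v), sd(v) / 10)))
  names(mets2) <- names(mets)
  rep2 <- quality_network_qc(cells, mets2, rep("neuron", n), seed = 27)
  expect_length(rep2$removed$cell_id[rep2$removed$reason == "quality_cluster"], 0)

  # a class below 30 cells is skipped with a warning
  expect_warning(
    quality_network_qc(profile_from_matrix(matrix(5L, 20, 30)),
                       mets[1:20, ], rep("glia", 20), seed = 28),
    "fewer than 30")
})

test_that("small quality clusters are removed with the small_cluster code", {
  set.seed(29)
  n <- 300
  mets <- data.frame(
    pct_oxphos = rbeta(n, 2, 60), pct_mito = rbeta(n, 1, 120),
    pct_ribo = rbeta(n, 2, 40), pct_ieg = rbeta(n, 1, 100),
    pct_top50 = rbeta(n, 10, 10), pct_lncRNA = rbeta(n, 1, 50),
    log2_genes = rnorm(n, 10, 0.2), log2_umis = rnorm(n, 12, 0.2))
  # 10 cells isolated in metric space but LOW in the flagged families,
  # so only the <15-cell rule can remove them
  tiny <- seq_len(10)
  mets$pct_top50[tiny] <- 0.99
  mets$pct_lncRNA[tiny] <- 0.6
  mets$pct_oxphos[tiny] <- 0.001
  cells <- profile_from_matrix(matrix(5L, n, 30))
  rep <- quality_network_qc(cells, mets, rep("neuron", n), k = 15, seed = 30)
  small <- rep$removed$cell_id[rep$removed$reason == "small_cluster"]
  expect_setequal(small, rownames(cells$counts)[tiny])
})
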