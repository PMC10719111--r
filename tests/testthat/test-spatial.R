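test_that("region references enforce the cell-count rules and rank markers in", {
  tr <- build_ground_truth(4, 150, n_regions = 2, doublet_rate = 0, seed = 60)
  cells <- simulate_cells(tr, 1200, 3000, seed = 61)
  lab <- cells$cell_meta$truth_type
  # starve T01 of region R01 cells: keep only 30 there (120+ elsewhere)
  t1_r1 <- which(lab == "T01" & cells$cell_meta$region == "R01")
  drop <- t1_r1[-seq_len(min(30, length(t1_r1)))]
  keep <- setdiff(seq_along(lab), drop)
  cells2 <- subset_cells(cells, keep)
  ref <- build_region_reference(cells2, lab[keep], "R01")
  expect_false("T01" %in% ref$types)
  expect_true(all(abs(rowSums(ref$theta) - 1) < 1e-9))
  # gene universe below the cap: the tailored list is everything
  expect_length(ref$tailored_genes, 150)
  # every reference type's own markers make the list trivially, and rank early
  mk <- tr$marker_table$gene[tr$marker_table$type %in% ref$types]
  expect_true(all(mk %in% ref$tailored_genes[seq_len(60)]))
  expect_error(build_region_reference(cells2, lab[keep], "R01",
                                      min_total = 1e6),
               "fewer than 2")
})

test_that("bead eligibility uses both UMI thresholds", {
  m <- rbind(c(100, 49, 0), c(130, 19, 251), c(150, 0, 0), c(120, 20, 9))
  colnames(m) <- c("t1", "t2", "other")
  beads <- structure(list(counts = Matrix::Matrix(m, sparse = TRUE),
                          bead_meta = data.frame(bead_id = paste0("b", 1:4),
                                                 region = "R01"),
                          gene_ids = colnames(m)),
                     class = "bead_matrix")
  rownames(beads$counts) <- beads$bead_meta$bead_id
  elig <- filter_beads(beads, c("t1", "t2"))
  expect_equal(unname(elig), c(FALSE,  # 149 total
                               TRUE,   # 400 total, 149 tailored
                               TRUE,   # 150 total all tailored
                               FALSE)) # 149 total
  elig2 <- filter_beads(beads, c("t1"))
  expect_equal(unname(elig2), c(FALSE, TRUE, TRUE, FALSE))
  # 19 tailored UMIs fails the tailored rule even with ample total
  m2 <- rbind(c(19, 0, 400))
  colnames(m2) <- colnames(m)
  beads2 <- beads; beads2$counts <- Matrix::Matrix(m2, sparse = TRUE)
  colnames(beads2$counts) <- colnames(m)
  expect_false(filter_beads(beads2, c("t1", "t2"))[1])
})

test_that("weight fitting recovers boundary, mixture and ridge limits", {
  ref <- reference_map()
  theta <- t(ref$theta)
  tr <- truth_map()
  # pure single-type bead against its own type: weight 1 at the boundary
  set.seed(62)
  y <- stats::rmultinom(1, 1000, tr$type_profiles["T01", ])[, 1]
  fit <- fit_weights(y, theta[, "T01", drop = FALSE], 1000)
  expect_equal(unname(fit$w), 1, tolerance = 1e-6)
  mu <- theta[, "T01"]
  ll_direct <- sum(y[y > 0] * log(1000 * mu[y > 0])) - 1000 * sum(mu)
  expect_equal(fit$loglik, ll_direct, tolerance = 1e-8)
  # 50/50 mixture recovered within 0.15 at depth 1000
  p <- (tr$type_profiles["T01", ] + tr$type_profiles["T02", ]) / 2
  errs <- replicate(10, {
    y2 <- stats::rmultinom(1, 1000, p)[, 1]
    f2 <- fit_weights(y2, theta[, c("T01", "T02")], 1000)
    max(abs(f2$w - 0.5))
  })
  expect_lt(mean(errs), 0.15)
  # overwhelming ridge drives the weights to zero
  f3 <- fit_weights(y, theta[, c("T01", "T02")], 1000, ridge = 1e6)
  expect_lt(sum(f3$w), 1e-3)
})

test_that("pair fits agree with a brute-force grid oracle", {
  ref <- reference_map()
  theta <- t(ref$theta)
  tr <- truth_map()
  set.seed(63)
  for (i in 1:5) {
    mix <- runif(1)
    p <- mix * tr$type_profiles["T03", ] + (1 - mix) * tr$type_profiles["T05", ]
    y <- stats::rmultinom(1, 800, p)[, 1]
    fit <- fit_weights(y, theta[, c("T03", "T05")], 800)
    # oracle: dense grid over (w1, w2) on the constrained triangle
    grid <- seq(0, 1, by = 0.005)
    best <- -Inf
    for (w1 in grid) for (w2 in grid[grid <= 1 - w1 + 1e-12]) {
      mu <- theta[, "T03"] * w1 + theta[, "T05"] * w2
      if (any(mu[y > 0] <= 0)) next
      ll <- sum(y[y > 0] * log(800 * mu[y > 0])) - 800 * sum(mu)
      if (ll > best) best <- ll
    }
    expect_gte(fit$loglik + 1e-4, best)
  }
})

test_that("prefiltering keeps the generating type and respects smallness", {
  ref <- reference_map()
  theta <- t(ref$theta)
  tr <- truth_map()
  set.seed(64)
  y <- stats::rmultinom(1, 1000, tr$type_profiles["T04", ])[, 1]
  pf <- prefilter_celltypes(y, theta, 1000)
  expect_true("T04" %in% pf$top10)
  expect_equal(names(which.max(pf$singlet_ll)), "T04")
  # a reference of <= 10 types puts every candidate in the top10
  expect_setequal(pf$top10, pf$candidates)
  expect_true(all(pf$top10 %in% pf$candidates))
})

test_that("pair scoring covers each admissible unordered pair exactly once", {
  ref <- reference_map()
  theta <- t(ref$theta)
  tr <- truth_map()
  set.seed(65)
  y <- stats::rmultinom(1, 800, tr$type_profiles["T02", ])[, 1]
  pf <- prefilter_celltypes(y, theta, 800)
  pt <- score_pairs(y, theta, 800, pf$candidates, pf$top10)
  expect_false(any(pt$type_a == pt$type_b))
  key <- apply(cbind(pmin(pt$type_a, pt$type_b), pmax(pt$type_a, pt$type_b)),
               1, paste, collapse = "|")
  expect_false(any(duplicated(key)))
  expect_equal(nrow(pt), choose(length(pf$candidates), 2))
  expect_false(is.unsorted(rev(pt$loglik)))
  # enlarging the candidate set never lowers the best score
  pt_small <- score_pairs(y, theta, 800, pf$candidates[1:4], pf$candidates[1:4])
  expect_gte(max(pt$loglik), max(pt_small$loglik) - 1e-9)
})

test_that("confidence scores follow the pair-frequency arithmetic", {
  mk <- function(a, b, ll) data.frame(type_a = a, type_b = b, loglik = ll,
                                      w_a = 0.5, w_b = 0.5,
                                      stringsAsFactors = FALSE)
  # one well-fitting pair: both members at the 0.5 maximum
  t1 <- rbind(mk("A", "B", 0), mk("C", "D", -100))
  c1 <- confidence_scores(t1)
  expect_equal(unname(c1$confidence[c("A", "B")]), c(0.5, 0.5))
  expect_setequal(c1$confident, c("A", "B"))
  # a hub type in three pairs: 3/6 = 0.5 vs 1/6 for the spokes
  t2 <- rbind(mk("A", "B", 0), mk("A", "C", -10), mk("A", "D", -20))
  c2 <- confidence_scores(t2)
  expect_equal(unname(c2$confidence["A"]), 0.5)
  expect_equal(unname(c2$confidence["B"]), 1 / 6)
  expect_setequal(c2$confident, "A")
  # a triangle: all three at 1/3, all confident
  t3 <- rbind(mk("A", "B", 0), mk("A", "C", -5), mk("B", "C", -10))
  c3 <- confidence_scores(t3)
  expect_equal(unname(c3$confidence[c("A", "B", "C")]), rep(1 / 3, 3))
  expect_setequal(c3$confident, c("A", "B", "C"))
  # the window boundary is inclusive at best - 30
  t4 <- rbind(mk("A", "B", 0), mk("A", "C", -30), mk("B", "D", -30.01))
  c4 <- confidence_scores(t4)
  expect_equal(nrow(c4$well_fitting), 2)
  expect_equal(sum(c4$confidence), 1)
})

test_that("prefilter plus pairs matches exhaustive scoring on small references", {
  ref <- reference_map()
  tr <- truth_map()
  types6 <- ref$types[seq_len(min(6, length(ref$types)))]
  theta <- t(ref$theta[types6, , drop = FALSE])
  set.seed(66)
  for (i in 1:5) {
    ty <- sample(types6, 2)
    mix <- runif(1, 0.3, 0.7)
    p <- mix * tr$type_profiles[ty[1], ] + (1 - mix) * tr$type_profiles[ty[2], ]
    y <- stats::rmultinom(1, 900, p)[, 1]
    pf <- prefilter_celltypes(y, theta, 900)
    pt <- score_pairs(y, theta, 900, pf$candidates, pf$top10)
    # oracle: exhaustive all-pairs scoring
    cmb <- utils::combn(types6, 2)
    lls <- apply(cmb, 2, function(pr)
      fit_weights(y, theta[, pr], 900)$loglik)
    want <- sort(cmb[, which.max(lls)])
    got <- sort(c(pt$type_a[1], pt$type_b[1]))
    expect_equal(got, want)
  }
})

test_that("bead mapping orchestrates filters, regions and empty input", {
  tr <- truth_map()
  ref <- reference_map()
  beads <- simulate_beads(tr, 40, 1000, doublet_fraction = 0, seed = 67)
  # one bead forced under the UMI floor
  m <- as.matrix(beads$counts)
  m[1, ] <- 0L; m[1, 1:5] <- 20L
  beads$counts <- Matrix::Matrix(m, sparse = TRUE)
  mp <- map_beads(beads, list(R01 = ref))
  expect_false(mp$beads$eligible[mp$beads$bead_id == "bead00001"])
  expect_false("bead00001" %in% mp$confidence$bead_id)
  # all eligible beads have confidences summing to exactly 1
  s <- tapply(mp$confidence$confidence, mp$confidence$bead_id, sum)
  expect_true(all(abs(s - 1) < 1e-12))
  expect_lte(max(mp$confidence$confidence), 0.5)
  # beads in a region without a reference are ineligible with a reason
  beads2 <- beads; beads2$bead_meta$region <- "R99"
  mp2 <- map_beads(beads2, list(R01 = ref))
  expect_true(all(!mp2$beads$eligible))
  expect_true(all(mp2$beads$reason == "no_reference"))
  # empty input is an empty mapping, not an error
  beads0 <- beads
  beads0$counts <- beads$counts[0, , drop = FALSE]
  beads0$bead_meta <- beads$bead_meta[0, , drop = FALSE]
  mp0 <- map_beads(beads0, list(R01 = ref))
  expect_null(mp0$beads)
})
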