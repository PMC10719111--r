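# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# 8-type two-region world used by clustering tests
truth8 <- function() fixture("truth8", function()
  build_ground_truth(8, 200, n_regions = 2, seed = 1))

cells8 <- function() fixture("cells8", function()
  simulate_cells(truth8(), 5000, 5000, seed = 2))

# single even-composition region used by mapping tests
truth_map <- function() fixture("truth_map", function()
  build_ground_truth(8, 200, n_regions = 1, region_tilt = Inf, seed = 11))

cells_map <- function() fixture("cells_map", function()
  simulate_cells(truth_map(), 3000, 5000, seed = 12))

reference_map <- function() fixture("reference_map", function() {
  cells <- cells_map()
  lab <- ifelse(cells$cell_meta$truth_doublet, NA, cells$cell_meta$truth_type)
  build_region_reference(cells, lab, "R01")
})

# build a cell_profile directly from a dense count matrix
profile_from_matrix <- function(m, region = "R01") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("c%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("g%03d", seq_len(ncol(m)))
  meta <- data.frame(cell_id = rownames(m), library_id = "L1", donor_id = "D1",
                     region = region, stringsAsFactors = FALSE)
  structure(list(counts = Matrix::Matrix(m, sparse = TRUE),
                 cell_meta = meta, gene_ids = colnames(m)),
            class = "cell_profile")
}

# brute-force marker-test oracle: the three criteria evaluated with
# stats::wilcox.test on dense arrays, one ordered cluster pair at a time
oracle_marker_pairs <- function(m, labels, alpha = 0.01, low_max = 0.10,
                                min_diff = 0.20) {
  cl <- sort(unique(labels))
  ngene <- ncol(m)
  out <- matrix(0L, length(cl), length(cl), dimnames = list(cl, cl))
  for (a in cl) for (b in cl) {
    if (a == b) next
    xa <- m[labels == a, , drop = FALSE]
    xb <- m[labels == b, , drop = FALSE]
    n_pass <- 0L
    for (j in seq_len(ngene)) {
      fa <- mean(xa[, j] > 0); fb <- mean(xb[, j] > 0)
      if (!(fb < low_max && fa >= fb + min_diff)) next
      p <- suppressWarnings(stats::wilcox.test(xa[, j], xb[, j],
                                               exact = FALSE,
                                               correct = FALSE)$p.value)
      if (is.finite(p) && p * ngene < alpha) n_pass <- n_pass + 1L
    }
    out[a, b] <- n_pass
  }
  out
}

# brute-force minimum set cover by exhaustive subset enumeration
oracle_min_cover_size <- function(on, off, target, max_size = 4) {
  others <- setdiff(rownames(on), target)
  cand <- colnames(on)[on[target, ]]
  if (length(cand) == 0) return(NA_integer_)
  for (k in seq_len(min(max_size, length(cand)))) {
    for (ix in utils::combn(length(cand), k, simplify = FALSE)) {
      covered <- vapply(others, function(u) any(off[u, cand[ix]]), FALSE)
      if (all(covered)) return(k)
    }
  }
  NA_integer_
}

# Holm step-down computed from first principles on sorted raw p-values
oracle_holm <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((n - seq_len(n) + 1) * p[o]))
  out <- numeric(n)
  out[o] <- adj
  out
}

# planted-module normalized fixture: anchor plus module genes at target r
planted_arg_matrix <- function(n, n_module, n_noise, r, seed) {
  set.seed(seed)
  anchor <- rnorm(n)
  mod <- vapply(seq_len(n_module), function(i)
    r * anchor + sqrt(1 - r^2) * rnorm(n), numeric(n))
  noise <- matrix(rnorm(n * n_noise), n)
  z <- cbind(anchor, mod, noise)
  colnames(z) <- c("Fos", paste0("Mod", seq_len(n_module)),
                   paste0("Noise", seq_len(n_noise)))
  z
}
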