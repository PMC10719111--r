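# Recursive cluster discovery: binomial variable-gene selection, sqrt
# transform, cosine kNN -> Jaccard SNN, Constant Potts Leiden resolution
# sweep with a sqrt(N) discard, and a discrete-marker termination test.

#' Select variable genes by deficit of detection under a binomial model
#'
#' For each gene, its relative bulk expression `p` (summed counts over total
#' UMIs) predicts, for a cell of depth `n`, a Poisson rate `lambda = n * p`
#' and hence an expected detection probability `1 - exp(-lambda)`. Genes whose
#' observed nonzero fraction falls at least `min_deficit` below the mean
#' expected detection are selected: such a deficit indicates that expression
#' is concentrated in a subpopulation rather than homogeneous.
#'
#' @param counts cells x genes count matrix (sparse or dense).
#' @param min_deficit required detection shortfall (default 0.05).
#' @return character vector of selected gene names (possibly empty).
#' @export
select_variable_genes <- function(counts, min_deficit = 0.05) {
  stopifnot(nrow(counts) >= 2)
  depth <- Matrix::rowSums(counts)
  total <- sum(depth)
  if (total <= 0) stop("matrix has no counts")
  p <- Matrix::colSums(counts) / total
  observed <- Matrix::colMeans(counts > 0)
  expected <- numeric(length(p))
  # block over genes to bound the n x g dense intermediate
  gsz <- max(1L, floor(2e6 / length(depth)))
  for (s in seq(1L, length(p), by = gsz)) {
    j <- s:min(s + gsz - 1L, length(p))
    expected[j] <- colMeans(1 - exp(-outer(depth, p[j])))
  }
  colnames(counts)[observed <= expected - min_deficit]
}

#' Build the cell-cell SNN graph used for one clustering round
#'
#' Counts are square-root transformed and restricted to the selected genes;
#' neighbours are found under cosine distance with `k` neighbours (self
#' excluded). Cells with no counts on the selected genes cannot be placed by
#' cosine distance there, so their neighbour lists are computed on the sqrt
#' of the full gene set instead.
#'
#' @param counts cells x genes count matrix.
#' @param genes selected variable genes (non-empty).
#' @param k neighbours per cell (default 50, capped below the cell count).
#' @return an `igraph` weighted SNN graph.
#' @export
build_snn <- function(counts, genes, k = 50) {
  stopifnot(length(genes) >= 1)
  k <- min(k, nrow(counts) - 1L)
  x <- sqrt(as.matrix(counts[, genes, drop = FALSE]))
  nn <- knn_indices(x, k, "cosine")
  empty <- which(rowSums(x) == 0)
  if (length(empty) > 0) {
    xf <- sqrt(as.matrix(counts))
    nrm <- sqrt(rowSums(xf^2)); nrm[nrm == 0] <- 1
    xf <- xf / nrm
    for (i in empty) {
      s <- drop(xf %*% xf[i, ]); s[i] <- -Inf
      nn[i, ] <- order(s, decreasing = TRUE)[seq_len(k)]
    }
  }
  snn_graph(nn)
}

#' Leiden resolution sweep under the Constant Potts Model
#'
#' Starting from a very low resolution (all cells in one cluster), the
#' resolution is increased along a fixed logarithmic grid until the partition
#' has at least two clusters whose largest/second-largest size ratio is at
#' most `max_ratio`. Clusters smaller than `sqrt(N)` of the current round are
#' then discarded. A graph that is not a single connected component at the
#' start indicates a homogeneous population (no resolution yields a single
#' cluster) and stops the sweep, as does grid exhaustion.
#'
#' @param graph weighted SNN graph.
#' @param resolutions sweep grid (default 40 log steps in [1e-6, 1]).
#' @param max_ratio largest/second-largest cluster size ratio bound.
#' @param seed integer seed for the Leiden refinement.
#' @return list with `status` ("split", "no_split" or "disconnected"),
#'   `membership` (for "split": integer labels, NA for discarded cells),
#'   `resolution`, and `discarded` (indices).
#' @export
leiden_sweep <- function(graph, resolutions = exp(seq(log(1e-6), log(1),
                                                      length.out = 40)),
                         max_ratio = 20, seed = 1) {
  n <- igraph::vcount(graph)
  if (n == 0) stop("empty graph")
  if (igraph::count_components(graph) > 1)
    return(list(status = "disconnected", membership = NULL,
                resolution = NA_real_, discarded = integer(0)))
  for (res in resolutions) {
    set.seed(seed)
    part <- igraph::cluster_leiden(graph, objective_function = "CPM",
                                   weights = igraph::E(graph)$weight,
                                   resolution = res, n_iterations = 3)
    memb <- igraph::membership(part)
    sizes <- sort(tabulate(memb), decreasing = TRUE)
    sizes <- sizes[sizes > 0]
    if (length(sizes) >= 2 && sizes[1] / sizes[2] <= max_ratio) {
      small <- which(tabulate(memb)[memb] < sqrt(n))
      memb2 <- memb
      memb2[small] <- NA
      if (length(unique(stats::na.omit(memb2))) >= 2) {
        keep_ids <- sort(unique(stats::na.omit(memb2)))
        memb2 <- match(memb2, keep_ids)
        return(list(status = "split", membership = memb2, resolution = res,
                    discarded = small))
      }
    }
  }
  list(status = "no_split", membership = NULL, resolution = NA_real_,
       discarded = integer(0))
}

# two-sided Mann-Whitney p-values for every gene, group A vs group B,
# normal approximation with tie correction (columns of x are genes)
mann_whitney_p <- function(x, in_a) {
  x <- as.matrix(x)
  n1 <- sum(in_a); n2 <- sum(!in_a); n <- n1 + n2
  p <- vapply(seq_len(ncol(x)), function(j) {
    r <- rank(x[, j])
    u <- sum(r[in_a]) - n1 * (n1 + 1) / 2
    ties <- table(x[, j])
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sig2 <- n1 * n2 / 12 * (n + 1 - tie_term)
    if (sig2 <= 0) return(1)
    z <- (u - n1 * n2 / 2) / sqrt(sig2)
    2 * stats::pnorm(-abs(z))
  }, numeric(1))
  p
}

#' Discrete-marker test between sibling clusters
#'
#' Every ordered pair of sibling clusters is compared gene by gene. A gene is
#' a discrete marker for the high-side cluster of a pair when (1) its
#' Mann-Whitney p-value is below `alpha` after Bonferroni correction over the
#' genes tested at this node, (2) its nonzero fraction in the low-side
#' cluster is below `low_max`, and (3) its nonzero fraction in the high-side
#' cluster exceeds the low side by at least `min_diff`. The partition is kept
#' only if every ordered pair has at least `n_required` passing genes, i.e.
#' each cluster is discretely separable from each sibling in both directions.
#'
#' @param counts cells x genes count matrix for the node being tested.
#' @param labels cluster labels (NAs ignored); at least 2 clusters.
#' @param alpha significance level before Bonferroni (default 0.01).
#' @param low_max maximum nonzero fraction on the low side (default 0.10,
#'   strict).
#' @param min_diff required detection-rate difference (default 0.20).
#' @param n_required markers needed per ordered pair (default 3).
#' @return list with `decision` ("keep"/"merge"), `pair_counts` (matrix of
#'   passing-gene counts, rows = high-side cluster), and `pairs` (long data
#'   frame of passing genes).
#' @export
test_cluster_markers <- function(counts, labels, alpha = 0.01, low_max = 0.10,
                                 min_diff = 0.20, n_required = 3) {
  ok <- !is.na(labels)
  counts <- counts[ok, , drop = FALSE]
  labels <- labels[ok]
  cl <- sort(unique(labels))
  if (length(cl) < 2) stop("need at least 2 clusters")
  if (min(table(labels)) < 2)
    return(list(decision = "merge", pair_counts = NULL, pairs = NULL))
  frac <- do.call(rbind, lapply(cl, function(g)
    Matrix::colMeans(counts[labels == g, , drop = FALSE] > 0)))
  rownames(frac) <- cl
  ngene <- ncol(counts)
  pair_counts <- matrix(0L, length(cl), length(cl), dimnames = list(cl, cl))
  rows <- list()
  for (a in seq_along(cl)) for (b in seq_along(cl)) {
    if (a == b) next
    # candidate markers high in cl[a], discretely off in cl[b]
    cand <- which(frac[b, ] < low_max & frac[a, ] >= frac[b, ] + min_diff)
    if (length(cand) == 0) next
    sel <- labels %in% cl[c(a, b)]
    p <- mann_whitney_p(counts[sel, cand, drop = FALSE],
                        labels[sel] == cl[a])
    pass <- cand[p * ngene < alpha]
    pair_counts[a, b] <- length(pass)
    if (length(pass))
      rows[[length(rows) + 1]] <- data.frame(
        high = cl[a], low = cl[b], gene = colnames(counts)[pass],
        p_bonf = pmin(1, p[match(pass, cand)] * ngene),
        frac_high = frac[a, pass], frac_low = frac[b, pass],
        stringsAsFactors = FALSE)
  }
  off <- pair_counts[row(pair_counts) != col(pair_counts)]
  decision <- if (all(off >= n_required)) "keep" else "merge"
  list(decision = decision, pair_counts = pair_counts,
       pairs = if (length(rows)) do.call(rbind, rows) else NULL)
}

# deterministic per-node seed below 2^31
node_seed <- function(master, node_id) {
  h <- sum(utf8ToInt(node_id) * (seq_along(utf8ToInt(node_id)) %% 7 + 1))
  (as.integer(master) + h * 1009L) %% 2147483647L
}

#' Recursive cluster discovery
#'
#' Applies one clustering round (variable genes, SNN, Leiden sweep, marker
#' test) recursively to each resulting cluster until a node is homogeneous
#' (no variable genes, a disconnected SNN graph, or an exhausted sweep) or
#' its children cannot be separated by at least `n_required` discrete markers
#' per sibling pair in both directions, in which case the children are merged
#' back. One exception: if the children of a merged level can themselves be
#' split one level further into marker-separable clusters, the split is
#' retained (a continuous first split masking discrete structure).
#'
#' @param cells a `cell_profile` object (QC-passed).
#' @param k SNN neighbours (default 50).
#' @param max_ratio Leiden sweep size-ratio bound (default 20).
#' @param n_required discrete markers required per sibling pair (default 3).
#' @param alpha Mann-Whitney significance level before Bonferroni.
#' @param min_cells nodes smaller than this are terminal (default 20).
#' @param max_depth recursion cap (default 20).
#' @param seed master seed; each node derives its own.
#' @return a `cluster_tree`: `nodes` (list), `leaves` (character ids),
#'   `assignments` (per-cell leaf id, NA = discarded), `markers` (per-parent
#'   passing-marker tables).
#' @export
iterative_cluster <- function(cells, k = 50, max_ratio = 20, n_required = 3,
                              alpha = 0.01, min_cells = 20, max_depth = 20,
                              seed = 1) {
  counts <- cells$counts
  n_all <- nrow(counts)
  nodes <- list()
  assignments <- rep(NA_character_, n_all)
  discarded <- logical(n_all)
  markers <- list()

  # perform one clustering round on a member set; returns leiden result with
  # membership relative to `members`, or a termination reason
  one_round <- function(members, node_seed_val) {
    sub <- counts[members, , drop = FALSE]
    genes <- select_variable_genes(sub)
    if (length(genes) == 0)
      return(list(status = "no_split", genes = genes))
    g <- build_snn(sub, genes, k)
    sw <- leiden_sweep(g, max_ratio = max_ratio, seed = node_seed_val)
    sw$genes <- genes
    sw
  }

  recurse <- function(node_id, members, depth) {
    if (depth > max_depth) stop("recursion depth cap exceeded at ", node_id)
    term <- function(reason) {
      nodes[[node_id]] <<- list(id = node_id, members = members,
                                n = length(members), reason = reason,
                                children = character(0))
      assignments[members] <<- node_id
    }
    if (length(members) < min_cells || length(members) < k + 2) {
      term("leaf"); return(invisible())
    }
    sw <- one_round(members, node_seed(seed, node_id))
    if (sw$status == "no_split") { term("no_split"); return(invisible()) }
    if (sw$status == "disconnected") { term("disconnected_trivial"); return(invisible()) }

    memb <- sw$membership
    mt <- test_cluster_markers(counts[members, , drop = FALSE], memb,
                               alpha = alpha, n_required = n_required)
    if (mt$decision == "merge") {
      # continuous-split exception: look exactly one level deeper
      finer <- memb
      offset <- max(memb, na.rm = TRUE)
      any_finer <- FALSE
      for (cl in sort(unique(stats::na.omit(memb)))) {
        sub_idx <- which(!is.na(memb) & memb == cl)
        if (length(sub_idx) < max(min_cells, k + 2)) next
        sw2 <- one_round(members[sub_idx],
                         node_seed(seed, paste0(node_id, ".x", cl)))
        if (sw2$status == "split") {
          finer[sub_idx] <- ifelse(is.na(sw2$membership), NA,
                                   offset + sw2$membership)
          offset <- max(finer, na.rm = TRUE)
          any_finer <- TRUE
        }
      }
      if (any_finer) {
        ids <- sort(unique(stats::na.omit(finer)))
        if (length(ids) >= 2) {
          finer <- match(finer, ids)
          mt2 <- test_cluster_markers(counts[members, , drop = FALSE], finer,
                                      alpha = alpha, n_required = n_required)
          if (mt2$decision == "keep") {
            memb <- finer
            mt <- mt2
          }
        }
      }
    }
    if (mt$decision == "merge") { term("no_markers_merged"); return(invisible()) }

    # accepted split: record node, discard ledger, recurse on children
    disc <- members[is.na(memb)]
    discarded[disc] <<- TRUE
    child_ids <- character(0)
    for (cl in sort(unique(stats::na.omit(memb)))) {
      child_ids <- c(child_ids, paste0(node_id, ".", cl))
    }
    nodes[[node_id]] <<- list(id = node_id, members = members,
                              n = length(members), reason = "split",
                              resolution = sw$resolution,
                              variable_genes = sw$genes,
                              n_discarded = length(disc),
                              children = child_ids)
    markers[[node_id]] <<- mt$pairs
    for (cl in sort(unique(stats::na.omit(memb)))) {
      recurse(paste0(node_id, ".", cl), members[which(!is.na(memb) & memb == cl)],
              depth + 1)
    }
  }

  recurse("root", seq_len(n_all), 1)
  leaves <- names(Filter(function(nd) length(nd$children) == 0, nodes))
  structure(list(nodes = nodes, leaves = leaves, assignments = assignments,
                 discarded = which(discarded), markers = markers,
                 n_cells = n_all),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat("cluster_tree:", length(x$leaves), "leaves over", x$n_cells, "cells;",
      length(x$discarded), "discarded\n")
  invisible(x)
}
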