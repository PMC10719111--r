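# Pseudocell construction, normalization, and the activity-regulated-gene
# analysis: anchor-correlation candidate selection, bipartite gene-group
# network with core-IEG extraction, ARG clustering and gene-set overlap.

#' Pseudocell target size for a cell type of n cells
#'
#' `s = min(200, max(20, n / 50))`: size scales with cell-type size between
#' a floor of 20 and a ceiling of 200 cells per pseudocell.
#'
#' @param n cells in the type (>= 1).
#' @return target size (real-valued).
#' @export
pseudocell_size <- function(n) {
  stopifnot(all(n >= 1))
  pmin(200, pmax(20, n / 50))
}

#' Aggregate cells into within-type pseudocells
#'
#' Per type: variable genes are selected, log-CPM expression is scaled, PCA
#' computed with components weighted by their variance explained, k-means
#' (k = round(n/s), at least 1) finds pseudocell centres, and cells take
#' their k-means centre, refined by one strict-majority smoothing pass over
#' the within-type kNN graph (a cell switches centre only when more than
#' half of its neighbours agree on another one), which relaxes the purely
#' spherical assignment at cluster boundaries without eroding centre
#' granularity. Raw UMI counts of member cells are summed per pseudocell;
#' pseudocells never span cell types. Types smaller than `2 * s` form a
#' single pseudocell.
#'
#' @param cells a `cell_profile`.
#' @param assignments per-cell type labels (NA cells are skipped).
#' @param groups optional per-cell group labels (e.g. region x class) carried
#'   onto pseudocells by majority.
#' @param n_pcs principal components (default 50; capped by dimensions).
#' @param knn neighbours for label propagation (default 10).
#' @param seed integer seed.
#' @return a `pseudocell_set`: `counts` (pseudocell x gene), `meta`
#'   (pseudocell id, type, group, n_cells), `membership` (per-cell pseudocell
#'   id).
#' @export
build_pseudocells <- function(cells, assignments, groups = NULL, n_pcs = 50,
                              knn = 10, seed = 1) {
  stopifnot(length(assignments) == nrow(cells$counts))
  if (is.null(groups)) groups <- rep("all", nrow(cells$counts))
  counts <- cells$counts
  membership <- rep(NA_character_, nrow(counts))
  withr_seed(seed, {
    for (ty in sort(unique(stats::na.omit(assignments)))) {
      idx <- which(!is.na(assignments) & assignments == ty)
      n <- length(idx)
      s <- pseudocell_size(n)
      k <- max(1L, round(n / s))
      if (n < 2 * s || k == 1) {
        membership[idx] <- paste0(ty, "_pc1")
        next
      }
      sub <- counts[idx, , drop = FALSE]
      genes <- select_variable_genes(sub)
      if (length(genes) < 2) {
        v <- apply(sub, 2, stats::var)
        genes <- colnames(sub)[order(v, decreasing = TRUE)[seq_len(min(50, ncol(sub)))]]
      }
      depth <- Matrix::rowSums(sub)
      x <- log2(as.matrix(sub[, genes, drop = FALSE]) / depth * 1e6 + 1)
      x <- scale(x)
      x[, !is.finite(colSums(x))] <- 0
      npc <- min(n_pcs, n - 1L, ncol(x))
      pc <- stats::prcomp(x, rank. = npc, center = FALSE, scale. = FALSE)
      varex <- pc$sdev[seq_len(npc)]^2 / sum(pc$sdev^2)
      scores <- sweep(pc$x, 2, varex, `*`)
      km <- stats::kmeans(scores, centers = k, nstart = 5, iter.max = 50)
      lab <- km$cluster
      nn <- knn_indices(scores, min(knn, n - 1L), "euclidean")
      smoothed <- vapply(seq_len(n), function(i) {
        tab <- tabulate(lab[nn[i, ]], k)
        m <- which.max(tab)
        if (tab[m] > ncol(nn) / 2 && m != lab[i]) m else lab[i]
      }, 1L)
      # smoothing must not erase a centre; keep the k-means partition if so
      if (length(unique(smoothed)) == k) lab <- smoothed
      membership[idx] <- paste0(ty, "_pc", lab)
    }
  })
  keep <- !is.na(membership)
  pcs <- sort(unique(membership[keep]))
  agg <- Matrix::sparseMatrix(i = match(membership[keep], pcs),
                              j = which(keep), x = 1,
                              dims = c(length(pcs), nrow(counts)))
  pc_counts <- as.matrix(agg %*% counts)
  rownames(pc_counts) <- pcs
  maj <- function(v) names(sort(table(v), decreasing = TRUE))[1]
  meta <- data.frame(
    pseudocell = pcs,
    type = vapply(pcs, function(p) maj(assignments[keep][membership[keep] == p]), ""),
    group = vapply(pcs, function(p) maj(groups[keep][membership[keep] == p]), ""),
    n_cells = as.integer(table(membership[keep])[pcs]),
    stringsAsFactors = FALSE)
  structure(list(counts = pc_counts, meta = meta, membership = membership),
            class = "pseudocell_set")
}

#' Normalize a pseudocell count matrix
#'
#' Counts per million per pseudocell, log2(x + 1), quantile normalization of
#' the pseudocell expression distributions to their mean empirical
#' distribution (ties by average rank), then per-gene standardization to
#' mean 0 / sd 1. Genes with zero variance are centred but not scaled and
#' are flagged.
#'
#' @param pcs a `pseudocell_set` (or pseudocell x gene count matrix).
#' @return list with `normalized` (pseudocell x gene), the
#'   `quantile_normalized` intermediate (before per-gene standardization),
#'   and `zero_var_genes`.
#' @export
normalize_pseudocells <- function(pcs) {
  m <- if (inherits(pcs, "pseudocell_set")) pcs$counts else as.matrix(pcs)
  if (nrow(m) < 2) stop("need at least 2 pseudocells")
  depth <- rowSums(m)
  if (any(depth == 0)) stop("zero-count pseudocell")
  lcpm <- log2(m / depth * 1e6 + 1)
  qn <- t(limma::normalizeQuantiles(t(lcpm), ties = TRUE))
  sds <- apply(qn, 2, stats::sd)
  z <- scale(qn)
  zero_var <- sds == 0
  z[, zero_var] <- scale(qn[, zero_var, drop = FALSE], scale = FALSE)
  z <- z[, , drop = FALSE]
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  dimnames(z) <- dimnames(m)
  dimnames(qn) <- dimnames(m)
  list(normalized = z, quantile_normalized = qn,
       zero_var_genes = colnames(m)[zero_var])
}

#' Candidate activity-regulated genes by anchor correlation
#'
#' Within each cell group (>= `min_pseudocells` pseudocells), every gene's
#' Pearson correlation with the anchor is computed across the group's
#' pseudocells. A gene is a candidate in that group when (1) r >= `r_min`,
#' (2) r is in the >= `q`-quantile of the gene's correlations with all
#' genes, and (3) the correlation is significant after Holm correction
#' within the group (adjusted p < `alpha`). The final list is the union over
#' groups; the anchor itself is excluded.
#'
#' @param normalized pseudocell x gene normalized matrix.
#' @param groups per-pseudocell group labels.
#' @param anchor anchor gene (default "Fos").
#' @param r_min,q,alpha the three criteria thresholds (0.3 / 0.995 / 0.05).
#' @param min_pseudocells minimum group size (default 10).
#' @return an `arg_table`: data frame per (gene, group) with `r`, `p_holm`,
#'   `r_quantile`, `candidate`; attribute `candidates` holds the union list.
#' @export
arg_candidates <- function(normalized, groups, anchor = "Fos", r_min = 0.3,
                           q = 0.995, alpha = 0.05, min_pseudocells = 10) {
  stopifnot(anchor %in% colnames(normalized),
            length(groups) == nrow(normalized))
  rows <- list()
  for (g in sort(unique(groups))) {
    sel <- groups == g
    if (sum(sel) < min_pseudocells) {
      warning("group ", g, " has fewer than ", min_pseudocells,
              " pseudocells; skipped")
      next
    }
    x <- normalized[sel, , drop = FALSE]
    keep <- apply(x, 2, stats::sd) > 0
    if (!keep[anchor]) next
    cc <- suppressWarnings(stats::cor(x[, keep, drop = FALSE]))
    r <- cc[, anchor]
    n <- sum(sel)
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
    p <- 2 * stats::pt(-abs(tt), n - 2)
    gene_ids <- setdiff(colnames(cc), anchor)
    p_holm <- stats::p.adjust(p[gene_ids], method = "holm")
    rq <- vapply(gene_ids, function(gn) {
      others <- setdiff(colnames(cc), gn)   # self-correlation excluded
      mean(cc[gn, others] <= cc[gn, anchor])
    }, numeric(1))
    rows[[g]] <- data.frame(
      gene = gene_ids, group = g, r = r[gene_ids], p_holm = p_holm,
      r_quantile = rq,
      candidate = r[gene_ids] >= r_min & rq >= q & p_holm < alpha,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(gene = character(0), group = character(0),
                      r = numeric(0), p_holm = numeric(0),
                      r_quantile = numeric(0), candidate = logical(0))
  rownames(tab) <- NULL
  structure(tab, candidates = sort(unique(tab$gene[tab$candidate])),
            class = c("arg_table", "data.frame"))
}

#' Bipartite ARG-group network, degrees and core immediate-early genes
#'
#' Incidence entries are `e = r + 1` (so all are >= 1 when r >= 0 is not
#' required); edges with `e < prune` are removed, gene degree is the count
#' of surviving edges, and the core set is `degree > core_degree`.
#'
#' @param table an `arg_table` (candidate rows are used).
#' @param prune edge-weight threshold (default 1.3; strict "less than"
#'   prunes, so r = 0.3 survives).
#' @param core_degree core-gene degree threshold (default 18, strict ">").
#' @return list with `edges` (gene, group, e), `degree` (named), `core`.
#' @export
arg_network <- function(table, prune = 1.3, core_degree = 18) {
  cand <- attr(table, "candidates")
  sub <- table[table$gene %in% cand, , drop = FALSE]
  sub$e <- sub$r + 1
  edges <- sub[sub$e >= prune, c("gene", "group", "e")]
  degree <- table(factor(edges$gene, levels = cand))
  list(edges = edges, degree = stats::setNames(as.integer(degree), names(degree)),
       core = names(degree)[degree > core_degree])
}

#' Cluster candidate ARGs on their per-group anchor-correlation profiles
#'
#' Ward (ward.D2) hierarchical clustering of the gene x group correlation
#' matrix (genes missing a group imputed 0), cut into exactly `k` clusters.
#'
#' @param table an `arg_table`.
#' @param k cluster count (default 7).
#' @return named integer vector of cluster labels over candidate genes.
#' @export
arg_clusters <- function(table, k = 7) {
  cand <- attr(table, "candidates")
  if (k > length(cand)) stop("k exceeds the number of candidate genes")
  groups <- sort(unique(table$group))
  m <- matrix(0, length(cand), length(groups),
              dimnames = list(cand, groups))
  sub <- table[table$gene %in% cand, ]
  m[cbind(match(sub$gene, cand), match(sub$group, groups))] <- sub$r
  hc <- stats::hclust(stats::dist(m), method = "ward.D2")
  stats::cutree(hc, k = k)
}

#' Fisher overlap test between two gene sets
#'
#' One-sided Fisher's exact test on the 2x2 overlap table within `universe`;
#' the p-value is Bonferroni-multiplied by `n_comparisons` and capped at 1.
#' The odds ratio is the sample cross-product ratio.
#'
#' @param set_a,set_b gene sets (subsets of `universe`).
#' @param universe gene universe.
#' @param n_comparisons Bonferroni factor (default 1).
#' @return list with `odds_ratio`, `p` (corrected), `overlap`.
#' @export
geneset_overlap <- function(set_a, set_b, universe, n_comparisons = 1) {
  if (length(universe) == 0) stop("empty universe")
  set_a <- intersect(set_a, universe); set_b <- intersect(set_b, universe)
  a <- length(intersect(set_a, set_b))
  b <- length(setdiff(set_a, set_b))
  cc <- length(setdiff(set_b, set_a))
  d <- length(universe) - a - b - cc
  p <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE),
                          alternative = "greater")$p.value
  list(odds_ratio = (a * d) / (b * cc), p = min(1, p * n_comparisons),
       overlap = a)
}
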