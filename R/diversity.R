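# Regional diversity and sharing statistics: coverage counts, weighted
# Jaccard region similarity, and dendrogram neighbourhood extraction.

# per-region confident-bead counts per type, from a bead_mapping
region_type_counts <- function(mapping) {
  conf <- mapping$confidence[mapping$confidence$confident, , drop = FALSE]
  bb <- mapping$beads[, c("bead_id", "region")]
  conf$region <- bb$region[match(conf$bead_id, bb$bead_id)]
  tab <- table(conf$region, conf$type)
  matrix(tab, nrow(tab), ncol(tab), dimnames = dimnames(tab))
}

#' Number of cell types covering a fraction of a region's mapped beads
#'
#' Types are sorted by descending confident-bead count; the statistic is the
#' minimal k whose running sum reaches `q` of the region's total.
#'
#' @param counts named vector of per-type confident-bead counts for one
#'   region (or a `bead_mapping`, with `region` given).
#' @param q coverage fraction (default 0.95).
#' @param region region id when `counts` is a mapping.
#' @return integer k.
#' @export
types_for_coverage <- function(counts, q = 0.95, region = NULL) {
  if (inherits(counts, "bead_mapping")) {
    m <- region_type_counts(counts)
    if (!region %in% rownames(m)) stop("region has no confidently mapped beads")
    counts <- m[region, ]
  }
  counts <- sort(counts[counts > 0], decreasing = TRUE)
  if (length(counts) == 0) stop("no confidently mapped beads")
  cum <- cumsum(counts)
  unname(which(cum >= q * sum(counts))[1])
}

#' Weighted Jaccard similarity between regions' cell-type compositions
#'
#' `sim(r, s) = sum_t min(w_rt, w_st) / sum_t max(w_rt, w_st)` on per-region
#' type weights. A `bead_mapping` input uses confident-bead counts normalized
#' within region; a plain weight matrix is used as given. Symmetric with unit
#' diagonal; an all-zero region is defined to have similarity 0 with every
#' other region. On 0/1 weight vectors the statistic reduces to the plain
#' Jaccard index.
#'
#' @param mapping a `bead_mapping`, or a region x type weight matrix.
#' @return region x region similarity matrix.
#' @export
region_similarity <- function(mapping) {
  if (inherits(mapping, "bead_mapping")) {
    w <- region_type_counts(mapping)
    rs <- rowSums(w)
    wn <- w / ifelse(rs > 0, rs, 1)
  } else {
    w <- as.matrix(mapping)
    wn <- w
  }
  if (nrow(w) < 2) stop("need at least 2 regions")
  n <- nrow(wn)
  sim <- diag(1, n)
  dimnames(sim) <- list(rownames(w), rownames(w))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    mx <- sum(pmax(wn[i, ], wn[j, ]))
    sim[i, j] <- sim[j, i] <- if (mx > 0) sum(pmin(wn[i, ], wn[j, ])) / mx else 0
  }
  sim
}

#' Agglomerative cell-type dendrogram from aggregated SNN connectivity
#'
#' Between-type connectivity is the mean SNN edge weight between the two
#' types' member cells (0 when no edge); average-linkage agglomeration runs
#' on `max(C) - C` as the dissimilarity.
#'
#' @param snn an `igraph` SNN graph over cells.
#' @param assignments per-cell type labels aligned with the graph's
#'   vertices; NAs ignored.
#' @param neuronal named logical vector flagging neuronal types (optional;
#'   defaults to all neuronal).
#' @return list with `hclust` (the tree), `connectivity`, `neuronal`.
#' @export
type_dendrogram <- function(snn, assignments, neuronal = NULL) {
  el <- igraph::as_edgelist(snn, names = FALSE)
  wt <- igraph::E(snn)$weight
  types <- sort(unique(stats::na.omit(assignments)))
  k <- length(types)
  idx <- match(assignments, types)
  conn <- matrix(0, k, k, dimnames = list(types, types))
  npair <- outer(tabulate(idx, k), tabulate(idx, k))
  diag(npair) <- tabulate(idx, k) * (tabulate(idx, k) - 1) / 2
  acc <- matrix(0, k, k)
  for (e in seq_along(wt)) {
    a <- idx[el[e, 1]]; b <- idx[el[e, 2]]
    if (is.na(a) || is.na(b)) next
    acc[a, b] <- acc[a, b] + wt[e]
    if (a != b) acc[b, a] <- acc[b, a] + wt[e]
  }
  conn <- acc / pmax(npair, 1)
  dimnames(conn) <- list(types, types)
  d <- stats::as.dist(max(conn) - conn)
  hc <- stats::hclust(d, method = "average")
  if (is.null(neuronal)) neuronal <- stats::setNames(rep(TRUE, k), types)
  list(hclust = hc, connectivity = conn, neuronal = neuronal)
}

# leaf sets of every internal node of an hclust, indexed by merge row
hclust_node_leaves <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    get <- function(v) if (v < 0) hc$labels[-v] else sets[[v]]
    sets[[i]] <- c(get(hc$merge[i, 1]), get(hc$merge[i, 2]))
  }
  sets
}

#' Proximate neighbourhood of a cell type within the dendrogram
#'
#' Starting from the index leaf, descendants of successively more distant
#' ancestors are aggregated. Aggregation stops before the step that would
#' push the set past `cap` types, or (for a neuronal index) before absorbing
#' a sibling set that is more than `max_nonneuronal` non-neuronal.
#'
#' @param dendro result of [type_dendrogram()] (or a list with `hclust` and
#'   `neuronal`).
#' @param index leaf type id.
#' @param cap maximum neighbourhood size (default 100).
#' @param max_nonneuronal sibling non-neuronal fraction bound (default 0.6).
#' @return character vector of type ids (always contains the index).
#' @export
dendrogram_neighbourhood <- function(dendro, index, cap = 100,
                                     max_nonneuronal = 0.6) {
  hc <- dendro$hclust
  neuronal <- dendro$neuronal
  if (!index %in% hc$labels) stop("index type not found: ", index)
  sets <- hclust_node_leaves(hc)
  # ancestor chain of the index leaf
  leaf_code <- -match(index, hc$labels)
  chain <- integer(0)
  node <- leaf_code
  repeat {
    parent <- which(hc$merge[, 1] == node | hc$merge[, 2] == node)
    if (length(parent) == 0) break
    chain <- c(chain, parent)
    node <- parent
  }
  current <- index
  index_neuronal <- isTRUE(neuronal[[index]])
  for (a in chain) {
    nxt <- sets[[a]]
    incoming <- setdiff(nxt, current)
    if (length(nxt) > cap) break
    if (index_neuronal && length(incoming) > 0 &&
        mean(!neuronal[incoming]) > max_nonneuronal) break
    current <- nxt
  }
  current
}
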