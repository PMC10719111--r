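# k-nearest-neighbour and shared-nearest-neighbour graph construction.
# The SNN edge weight between two cells is the Jaccard similarity of their
# kNN sets (self excluded); zero-weight pairs carry no edge.

#' k-nearest neighbours under cosine or Euclidean distance
#'
#' @param x numeric matrix, rows are observations.
#' @param k neighbours per row (self excluded); must be < nrow(x).
#' @param metric "cosine" or "euclidean".
#' @param block row-block size used to bound the distance-matrix memory.
#' @return integer matrix n x k of neighbour row indices.
#' @export
knn_indices <- function(x, k, metric = c("cosine", "euclidean"), block = 1024L) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  n <- nrow(x)
  if (k >= n) stop("k must be smaller than the number of rows")
  if (metric == "cosine") {
    nrm <- sqrt(rowSums(x^2))
    nrm[nrm == 0] <- 1
    x <- x / nrm
  }
  out <- matrix(0L, n, k)
  sq <- if (metric == "euclidean") rowSums(x^2) else NULL
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    s <- tcrossprod(x[idx, , drop = FALSE], x)   # similarity / inner product
    if (metric == "euclidean") {
      s <- -(sq[idx] - 2 * s + rep(sq, each = length(idx)))  # negative squared dist
    }
    s[cbind(seq_along(idx), idx)] <- -Inf        # exclude self
    for (j in seq_along(idx)) {
      o <- order(s[j, ], decreasing = TRUE)[seq_len(k)]
      out[idx[j], ] <- o
    }
  }
  out
}

#' Shared-nearest-neighbour graph from kNN sets
#'
#' Edge weight between rows i and j is `|N_i intersect N_j| / |N_i union N_j|`
#' over their k-neighbour sets. All pairs with a nonzero overlap receive an
#' edge, not only kNN pairs.
#'
#' @param nn integer matrix from [knn_indices()].
#' @return an `igraph` weighted undirected graph on `nrow(nn)` vertices.
#' @export
snn_graph <- function(nn) {
  n <- nrow(nn); k <- ncol(nn)
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn),
                              x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)             # |N_i intersect N_j|
  shared <- methods::as(shared, "TsparseMatrix")
  keep <- shared@i < shared@j
  i <- shared@i[keep] + 1L; j <- shared@j[keep] + 1L
  inter <- shared@x[keep]
  w <- inter / (2 * k - inter)                  # |A|=|B|=k so |union| = 2k - inter
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(i, j))
  igraph::E(g)$weight <- w
  g
}
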