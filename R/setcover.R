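# Minimal combinatorial marker-gene discovery as an exactly solved set-cover
# problem, plus gene-family enrichment of the chosen markers.

#' Binarize per-type detection fractions into on/off calls
#'
#' A gene is "on" in a type when its nonzero fraction is at least `tau_on`,
#' "off" when at most `tau_off`; intermediate fractions are neither.
#'
#' @param fractions type x gene matrix of nonzero fractions in [0, 1].
#' @param tau_on,tau_off thresholds, `0 <= tau_off < tau_on <= 1`
#'   (defaults 0.5 / 0.1, mirroring the discrete-marker criteria).
#' @return list with logical matrices `on` and `off` and the thresholds.
#' @export
binarize_expression <- function(fractions, tau_on = 0.5, tau_off = 0.1) {
  stopifnot(tau_off >= 0, tau_off < tau_on, tau_on <= 1)
  fractions <- as.matrix(fractions)
  list(on = fractions >= tau_on, off = fractions <= tau_off,
       fractions = fractions, tau_on = tau_on, tau_off = tau_off)
}

# exact minimum set cover by depth-first branch and bound.
# sets: list of integer vectors (elements covered by each candidate);
# universe: integers to cover. Returns indices of a minimum cover or NULL.
min_set_cover <- function(sets, n_universe, max_size) {
  if (n_universe == 0) return(integer(0))
  cover_any <- unique(unlist(sets))
  if (length(cover_any) < n_universe) return(NULL)
  # greedy upper bound
  greedy <- integer(0)
  uncovered <- seq_len(n_universe)
  repeat {
    gains <- vapply(sets, function(s) length(intersect(s, uncovered)), 0L)
    best <- which.max(gains)
    if (gains[best] == 0) break
    greedy <- c(greedy, best)
    uncovered <- setdiff(uncovered, sets[[best]])
    if (length(uncovered) == 0) break
  }
  best_size <- if (length(uncovered) == 0) length(greedy) else Inf
  best_sol <- if (is.finite(best_size)) greedy else NULL
  max_size <- min(max_size, best_size)
  ord <- order(vapply(sets, length, 0L), decreasing = TRUE)
  set_sizes <- vapply(sets, length, 0L)
  dfs <- function(chosen, uncovered, avail) {
    if (length(uncovered) == 0) {
      if (length(chosen) < best_size) {
        best_size <<- length(chosen); best_sol <<- chosen
      }
      return(invisible())
    }
    if (length(chosen) + 1 > min(best_size - 1, max_size)) return(invisible())
    gains <- vapply(avail, function(k) length(intersect(sets[[k]], uncovered)), 0L)
    if (max(gains, 0) == 0) return(invisible())
    # lower bound: remaining elements / largest available gain
    lb <- ceiling(length(uncovered) / max(gains))
    if (length(chosen) + lb >= min(best_size, max_size + 1)) return(invisible())
    # branch on an uncovered element with fewest covering sets (most constrained)
    cover_count <- vapply(uncovered, function(e)
      sum(vapply(avail, function(k) e %in% sets[[k]], FALSE)), 0L)
    if (any(cover_count == 0)) return(invisible())
    e <- uncovered[which.min(cover_count)]
    cands <- avail[vapply(avail, function(k) e %in% sets[[k]], FALSE)]
    cands <- cands[order(gains[match(cands, avail)], decreasing = TRUE)]
    for (k in cands) {
      dfs(c(chosen, k), setdiff(uncovered, sets[[k]]), setdiff(avail, k))
    }
  }
  dfs(integer(0), seq_len(n_universe), ord)
  if (is.infinite(best_size) || best_size > max_size) NULL else sort(best_sol)
}

#' Minimal marker set uniquely defining one cell type
#'
#' The universe is every other type; a candidate gene (one that is "on" in
#' the target) covers another type when it is "off" there. The function
#' returns a minimum-cardinality cover solved exactly by branch and bound,
#' so the selected genes are all on in the target while every other type is
#' off for at least one of them. Among covers of minimal size, ties are
#' broken by the largest summed detection-fraction margin
#' (target fraction minus the mean fraction elsewhere) and then by
#' lexicographic gene order, enumerated exhaustively when the candidate pool
#' allows.
#'
#' @param target type id.
#' @param binarized result of [binarize_expression()].
#' @param max_size largest admissible cover (default 8); types needing more
#'   are reported infeasible.
#' @param enumerate_cap maximum number of size-k subsets examined for exact
#'   tie-breaking (default 5e4).
#' @return list with `type`, `genes`, `size`, `feasible`, and `certificate`
#'   (for each other type, one selected gene distinguishing it).
#' @export
minimal_marker_set <- function(target, binarized, max_size = 8,
                               enumerate_cap = 5e4) {
  on <- binarized$on; off <- binarized$off
  stopifnot(target %in% rownames(on))
  others <- setdiff(rownames(on), target)
  cand <- colnames(on)[on[target, ]]
  infeasible <- list(type = target, genes = character(0), size = NA_integer_,
                     feasible = FALSE, certificate = NULL)
  if (length(cand) == 0) return(infeasible)
  sets <- lapply(cand, function(g) which(off[others, g]))
  sol <- min_set_cover(sets, length(others), max_size)
  if (is.null(sol)) return(infeasible)
  k <- length(sol)
  genes <- cand[sol]
  # exact tie-breaking among all minimal covers when enumerable
  if (k >= 1 && choose(length(cand), k) <= enumerate_cap) {
    combs <- utils::combn(length(cand), k, simplify = FALSE)
    is_cover <- vapply(combs, function(ix)
      length(unique(unlist(sets[ix]))) == length(others), FALSE)
    covers <- combs[is_cover]
    margins <- vapply(covers, function(ix) {
      sum(binarized$fractions[target, cand[ix]] -
            colMeans(binarized$fractions[others, cand[ix], drop = FALSE]))
    }, numeric(1))
    best <- which(margins == max(margins))
    keys <- vapply(covers[best], function(ix)
      paste(sort(cand[ix]), collapse = "|"), character(1))
    genes <- sort(cand[covers[best][[order(keys)[1]]]])
  }
  cert <- vapply(others, function(u) genes[which(off[u, genes])[1]], character(1))
  list(type = target, genes = genes, size = k, feasible = TRUE,
       certificate = cert)
}

#' Minimal marker sets for every type
#'
#' @param binarized result of [binarize_expression()].
#' @param max_size per-type cover cap (default 8).
#' @return a `marker_cover` object: list of per-type results plus a summary
#'   data frame (`type`, `size`, `feasible`, `genes` collapsed).
#' @export
marker_cover_all <- function(binarized, max_size = 8) {
  res <- lapply(rownames(binarized$on), minimal_marker_set,
                binarized = binarized, max_size = max_size)
  names(res) <- rownames(binarized$on)
  summary <- data.frame(
    type = names(res),
    size = vapply(res, function(r) as.integer(r$size), 1L),
    feasible = vapply(res, function(r) r$feasible, FALSE),
    genes = vapply(res, function(r) paste(r$genes, collapse = ";"), ""),
    stringsAsFactors = FALSE)
  structure(list(covers = res, summary = summary), class = "marker_cover")
}

#' Gene-family enrichment among selected minimal markers
#'
#' One-sided Fisher's exact test of family membership among genes selected in
#' any minimal cover versus the unselected remainder of the universe; the
#' odds ratio reported is the sample cross-product ratio.
#'
#' @param covers a `marker_cover` object (or list of cover entries).
#' @param families named list of gene-id vectors.
#' @param universe gene universe (default: all binarized genes).
#' @return data frame with family, counts, odds ratio and p-value.
#' @export
family_enrichment <- function(covers, families, universe) {
  if (inherits(covers, "marker_cover")) covers <- covers$covers
  selected <- unique(unlist(lapply(covers, function(r) r$genes)))
  if (length(selected) == 0) {
    warning("no selected genes; all enrichment tests skipped")
    return(data.frame())
  }
  rows <- lapply(names(families), function(fam) {
    fg <- intersect(families[[fam]], universe)
    if (length(fg) == 0) {
      warning("family ", fam, " absent from universe; skipped")
      return(NULL)
    }
    a <- length(intersect(selected, fg))
    b <- length(setdiff(selected, fg))
    cc <- length(setdiff(fg, selected))
    d <- length(universe) - a - b - cc
    or <- (a * d) / (b * cc)   # may be Inf/NaN on degenerate margins
    p <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE),
                            alternative = "greater")$p.value
    data.frame(family = fam, selected_in = a, selected_out = b,
               unselected_in = cc, unselected_out = d,
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
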