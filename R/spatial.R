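# Bead-level cell-type decomposition: per-region references with tailored
# gene lists, ridge-regularized prefiltering, exhaustive top-10 pair scoring
# under a Poisson likelihood, and the pair-frequency confidence score.

#' Build a per-region cell-type reference
#'
#' Types are admitted to a region's reference when they have at least
#' `min_total` cells overall and at least `min_region` cells from that
#' region's libraries. `theta` rows are per-type mean count vectors
#' normalized to proportions. The tailored gene list ranks genes by their
#' minimum one-vs-rest Mann-Whitney p-value across the reference's types,
#' truncated at `max_genes`.
#'
#' @param cells a `cell_profile` with region tags in `cell_meta$region`.
#' @param assignments per-cell type labels (NA = unassigned).
#' @param region the region id to build the reference for.
#' @param min_region,min_total cell-count admission rules (defaults 50/100).
#' @param max_genes tailored list cap (default 5000).
#' @return a `region_reference`: `types`, `theta` (type x gene, rows sum to
#'   1), `cells_per_type`, `tailored_genes`, `region`.
#' @export
build_region_reference <- function(cells, assignments, region,
                                   min_region = 50, min_total = 100,
                                   max_genes = 5000) {
  stopifnot(length(assignments) == nrow(cells$counts))
  ok <- !is.na(assignments)
  total <- table(assignments[ok])
  in_region <- table(assignments[ok & cells$cell_meta$region == region])
  eligible <- names(total)[total >= min_total &
                           names(total) %in% names(in_region)[in_region >= min_region]]
  if (length(eligible) < 2)
    stop("region ", region, " has fewer than 2 eligible types")
  counts <- cells$counts
  theta <- do.call(rbind, lapply(eligible, function(t) {
    v <- Matrix::colMeans(counts[ok & assignments == t, , drop = FALSE])
    v / sum(v)
  }))
  rownames(theta) <- eligible

  # tailored list: min one-vs-rest Mann-Whitney p per gene within the reference
  ref_cells <- which(ok & assignments %in% eligible)
  sub <- counts[ref_cells, , drop = FALSE]
  lab <- assignments[ref_cells]
  minp <- rep(Inf, ncol(counts))
  for (t in eligible) {
    p <- mann_whitney_p(sub, lab == t)
    minp <- pmin(minp, p)
  }
  tailored <- colnames(counts)[order(minp)][seq_len(min(max_genes, ncol(counts)))]
  structure(list(types = eligible, theta = theta,
                 cells_per_type = as.integer(total[eligible]),
                 tailored_genes = tailored, region = region),
            class = "region_reference")
}

#' Bead eligibility filter
#'
#' A bead is eligible when it has at least `min_total` UMIs across all genes
#' and at least `min_tailored` UMIs within the tailored gene list.
#'
#' @param beads a `bead_matrix`.
#' @param tailored_genes the reference's tailored gene list.
#' @param min_total,min_tailored UMI thresholds (defaults 150/20).
#' @return logical vector, one flag per bead.
#' @export
filter_beads <- function(beads, tailored_genes, min_total = 150,
                         min_tailored = 20) {
  tot <- Matrix::rowSums(beads$counts)
  tail_tot <- Matrix::rowSums(beads$counts[, intersect(tailored_genes,
                                                       colnames(beads$counts)),
                                           drop = FALSE])
  tot >= min_total & tail_tot >= min_tailored
}

#' Fit non-negative mixture weights for one bead under a Poisson model
#'
#' Maximizes `sum_g [y_g * log(n * mu_g) - n * mu_g]` with
#' `mu_g = sum_t w_t * theta_{t,g}`, subject to `w >= 0` and `sum(w) <= 1`,
#' minus a ridge penalty `ridge * n * sum(w^2)`. `n` is the bead's total
#' depth. Solved by projected gradient ascent with backtracking; the returned
#' log-likelihood is unpenalized.
#'
#' @param y bead counts over the model's genes.
#' @param theta genes x types matrix of reference proportions (columns are
#'   types, restricted to the same genes as `y`).
#' @param depth bead total UMIs (scales the proportions).
#' @param ridge ridge strength (>= 0).
#' @param tol convergence tolerance on the objective (default 1e-8).
#' @param max_iter iteration cap (default 1000).
#' @return list with `w` (named weights), `loglik` (unpenalized), and
#'   `converged`.
#' @export
fit_weights <- function(y, theta, depth, ridge = 0, tol = 1e-8,
                        max_iter = 1000) {
  theta <- as.matrix(theta)
  K <- ncol(theta)
  stopifnot(K >= 1, length(y) == nrow(theta))
  pos <- y > 0
  if (ridge == 0 && K == 1) {
    # closed form: ll is concave in the single weight, optimum at the
    # boundary-capped ratio of observed to expected totals
    ct <- sum(theta[, 1])
    w1 <- min(1, sum(y) / (depth * ct))
    mu <- theta[, 1] * w1
    ll <- sum(y[pos] * log(depth * mu[pos])) - depth * sum(mu)
    return(list(w = stats::setNames(w1, colnames(theta)), loglik = ll,
                converged = TRUE))
  }
  if (ridge == 0 && K == 2) {
    # box reparameterization w = (s*m, s*(1-m)) with s, m in [0,1]
    fn <- function(par) {
      w <- c(par[1] * par[2], par[1] * (1 - par[2]))
      mu <- drop(theta %*% w)
      if (any(mu[pos] <= 0)) return(1e300)
      -(sum(y[pos] * log(depth * mu[pos])) - depth * sum(mu))
    }
    gr <- function(par) {
      w <- c(par[1] * par[2], par[1] * (1 - par[2]))
      mu <- drop(theta %*% w)
      r <- ifelse(mu > 0, y / pmax(mu, 1e-300), 0)
      gw <- drop(crossprod(theta, r - depth))
      -c(gw[1] * par[2] + gw[2] * (1 - par[2]),
         par[1] * (gw[1] - gw[2]))
    }
    op <- stats::optim(c(0.9, 0.5), fn, gr, method = "L-BFGS-B",
                       lower = c(1e-12, 0), upper = c(1, 1),
                       control = list(factr = 10))
    w <- c(op$par[1] * op$par[2], op$par[1] * (1 - op$par[2]))
    mu <- drop(theta %*% w)
    ll <- sum(y[pos] * log(depth * mu[pos])) - depth * sum(mu)
    return(list(w = stats::setNames(w, colnames(theta)), loglik = ll,
                converged = op$convergence == 0))
  }
  obj <- function(w) {
    mu <- drop(theta %*% w)
    if (any(mu[pos] <= 0)) return(-Inf)
    sum(y[pos] * log(depth * mu[pos])) - depth * sum(mu) -
      ridge * depth * sum(w^2)
  }
  grad <- function(w) {
    mu <- drop(theta %*% w)
    r <- ifelse(mu > 0, y / pmax(mu, 1e-300), 0)
    drop(crossprod(theta, r - depth)) - 2 * ridge * depth * w
  }
  # projection onto {w >= 0, sum(w) <= 1}
  proj <- function(w) {
    w <- pmax(w, 0)
    if (sum(w) <= 1) return(w)
    u <- sort(w, decreasing = TRUE)
    css <- cumsum(u)
    rho <- max(which(u > (css - 1) / seq_len(K)))
    pmax(w - (css[rho] - 1) / rho, 0)
  }
  w <- rep(min(1, 0.99) / K, K)
  f <- obj(w)
  step <- 1 / (depth * max(colSums(theta)))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    g <- grad(w)
    s <- step
    repeat {
      w_new <- proj(w + s * g)
      f_new <- obj(w_new)
      if (f_new >= f - 1e-12 || s < 1e-18) break
      s <- s / 2
    }
    if (!is.finite(f_new)) stop("non-finite objective in fit_weights")
    if (abs(f_new - f) < tol * (abs(f) + 1)) {
      w <- w_new; f <- f_new; converged <- TRUE; break
    }
    if (f_new > f) step <- s * 2 else step <- s
    w <- w_new; f <- f_new
  }
  if (!converged && max_iter >= 1000)
    warning("fit_weights did not converge to tolerance")
  mu <- drop(theta %*% w)
  ll <- sum(y[pos] * log(depth * mu[pos])) - depth * sum(mu)
  list(w = stats::setNames(w, colnames(theta)), loglik = ll,
       converged = converged)
}

#' Prefilter candidate cell types for one bead
#'
#' Runs the full-mode fit with the two ridge strengths and every single-type
#' fit; candidates are the union of types with ridge-fit weight above
#' `w_min` and the best single-type fits. The `top10` are the 10 candidates
#' ranked most likely (singlet log-likelihood, ties broken by the larger
#' ridge-fit weight).
#'
#' @param y,theta,depth as in [fit_weights()]; `theta` spans the full
#'   reference.
#' @param ridges the two ridge strengths (default `c(0.01, 0.001)`).
#' @param w_min support threshold on ridge-fit weights (default 0.01).
#' @return list with `candidates`, `top10`, `singlet_ll` (named vector).
#' @export
prefilter_celltypes <- function(y, theta, depth, ridges = c(0.01, 0.001),
                                w_min = 0.01) {
  types <- colnames(theta)
  support <- character(0)
  ridge_w <- rep(0, length(types)); names(ridge_w) <- types
  for (r in ridges) {
    fit <- fit_weights(y, theta, depth, ridge = r)
    support <- union(support, types[fit$w > w_min])
    ridge_w <- pmax(ridge_w, fit$w)
  }
  singlet_ll <- vapply(types, function(t)
    fit_weights(y, theta[, t, drop = FALSE], depth)$loglik, numeric(1))
  best_singlets <- types[order(singlet_ll, decreasing = TRUE)][
    seq_len(min(10, length(types)))]
  candidates <- union(support, best_singlets)
  if (length(candidates) < 2) candidates <- types
  ord <- order(singlet_ll[candidates], ridge_w[candidates], decreasing = TRUE)
  top10 <- candidates[ord][seq_len(min(10, length(candidates)))]
  list(candidates = candidates, top10 = top10, singlet_ll = singlet_ll)
}

#' Score admissible cell-type pairs for one bead
#'
#' Every unordered pair with at least one member in the top-10 list (pairs
#' within the top 10, and one-from-top-10 x one-from-the-rest) is fitted with
#' [fit_weights()] at ridge 0 and its unpenalized log-likelihood recorded.
#'
#' @param y,theta,depth as in [fit_weights()].
#' @param candidates,top10 from [prefilter_celltypes()].
#' @return data frame `type_a`, `type_b`, `loglik`, `w_a`, `w_b`, sorted by
#'   descending log-likelihood.
#' @export
score_pairs <- function(y, theta, depth, candidates, top10) {
  stopifnot(length(candidates) >= 2)
  prs <- list()
  for (i in seq_along(candidates)) for (j in seq_along(candidates)) {
    if (i >= j) next
    a <- candidates[i]; b <- candidates[j]
    if (!(a %in% top10) && !(b %in% top10)) next
    prs[[length(prs) + 1]] <- c(a, b)
  }
  rows <- lapply(prs, function(pr) {
    fit <- tryCatch(fit_weights(y, theta[, pr, drop = FALSE], depth),
                    error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    data.frame(type_a = pr[1], type_b = pr[2], loglik = fit$loglik,
               w_a = fit$w[1], w_b = fit$w[2], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  out[order(-out$loglik), , drop = FALSE]
}

#' Pair-frequency confidence scores
#'
#' The well-fitting set is every pair whose log-likelihood is within
#' `window` of the best pair. Each type's confidence is its number of
#' occurrences in well-fitting pairs divided by the total occurrences of all
#' types (twice the number of pairs), so confidences sum to 1 and a single
#' type reaches at most 0.5. Types above `threshold` are "confident".
#'
#' @param pair_table from [score_pairs()].
#' @param window log-likelihood window (default 30, natural log).
#' @param threshold confidence threshold (default 0.3).
#' @return list with `confidence` (named, sums to 1), `confident` (ids),
#'   `well_fitting` (subset of the pair table), `best_pair`.
#' @export
confidence_scores <- function(pair_table, window = 30, threshold = 0.3) {
  stopifnot(nrow(pair_table) >= 1)
  best <- max(pair_table$loglik)
  wf <- pair_table[pair_table$loglik >= best - window, , drop = FALSE]
  occ <- table(c(wf$type_a, wf$type_b))
  conf <- as.numeric(occ) / (2 * nrow(wf))
  names(conf) <- names(occ)
  list(confidence = conf,
       confident = names(conf)[conf > threshold],
       well_fitting = wf,
       best_pair = unlist(pair_table[1, c("type_a", "type_b")], use.names = FALSE))
}

#' Decompose all beads of a region against its reference
#'
#' Orchestrates eligibility filtering, prefiltering, pair scoring and
#' confidence scoring per bead. Beads in regions without a reference are
#' marked ineligible.
#'
#' @param beads a `bead_matrix`.
#' @param references named list of `region_reference` objects (names are
#'   region ids).
#' @param window,threshold confidence parameters (defaults 30 / 0.3).
#' @return a `bead_mapping`: `beads` data frame (bead id, region, eligible,
#'   best pair, best-pair weights), `confidence` long data frame (bead id,
#'   type, confidence, confident flag).
#' @export
map_beads <- function(beads, references, window = 30, threshold = 0.3) {
  meta <- beads$bead_meta
  n <- nrow(beads$counts)
  bead_rows <- vector("list", n)
  conf_rows <- vector("list", n)
  for (region in unique(meta$region)) {
    in_region <- which(meta$region == region)
    ref <- references[[region]]
    if (is.null(ref)) {
      bead_rows[in_region] <- lapply(in_region, function(i)
        data.frame(bead_id = meta$bead_id[i], region = region,
                   eligible = FALSE, reason = "no_reference",
                   type_a = NA, type_b = NA, w_a = NA_real_, w_b = NA_real_,
                   stringsAsFactors = FALSE))
      next
    }
    elig <- filter_beads(beads, ref$tailored_genes)
    genes <- intersect(ref$tailored_genes, colnames(beads$counts))
    theta <- t(ref$theta[, genes, drop = FALSE])   # genes x types
    for (i in in_region) {
      if (!elig[i]) {
        bead_rows[[i]] <- data.frame(bead_id = meta$bead_id[i],
                                     region = region, eligible = FALSE,
                                     reason = "low_umi", type_a = NA,
                                     type_b = NA, w_a = NA_real_,
                                     w_b = NA_real_, stringsAsFactors = FALSE)
        next
      }
      y <- beads$counts[i, genes]
      depth <- sum(beads$counts[i, ])
      pf <- prefilter_celltypes(y, theta, depth)
      pt <- score_pairs(y, theta, depth, pf$candidates, pf$top10)
      cs <- confidence_scores(pt, window, threshold)
      bead_rows[[i]] <- data.frame(bead_id = meta$bead_id[i], region = region,
                                   eligible = TRUE, reason = "",
                                   type_a = pt$type_a[1], type_b = pt$type_b[1],
                                   w_a = pt$w_a[1], w_b = pt$w_b[1],
                                   stringsAsFactors = FALSE)
      conf_rows[[i]] <- data.frame(bead_id = meta$bead_id[i],
                                   type = names(cs$confidence),
                                   confidence = as.numeric(cs$confidence),
                                   confident = cs$confidence > threshold,
                                   stringsAsFactors = FALSE)
    }
  }
  structure(list(beads = do.call(rbind, Filter(Negate(is.null), bead_rows)),
                 confidence = do.call(rbind, Filter(Negate(is.null), conf_rows)),
                 threshold = threshold),
            class = "bead_mapping")
}

#' @export
print.bead_mapping <- function(x, ...) {
  cat("bead_mapping:", nrow(x$beads), "beads,", sum(x$beads$eligible),
      "eligible\n")
  invisible(x)
}
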