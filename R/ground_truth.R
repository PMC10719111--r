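#' Build a ground-truth specification for synthetic atlas data
#'
#' Constructs the latent structure that the simulators draw from: a rooted
#' hierarchy of cell types, per-type expression profiles (probability vectors
#' over a shared gene universe), a table of discrete marker genes, per-region
#' cell-type compositions and, optionally, a latent activity program anchored
#' on a `Fos` stand-in gene.
#'
#' Marker semantics: each type receives `markers_per_type` private genes whose
#' detection frequency (fraction of cells with nonzero counts at the reference
#' depth `depth_ref`) is `on_fraction` in the home type and `on_fraction/fold`
#' in every other type, i.e. `fold` is the fold difference in detection
#' frequency between the home type and the rest. Expression rates are solved
#' from the Poisson detection identity `P(x > 0) = 1 - exp(-depth * p)`.
#'
#' The gene universe always contains designated quality-covariate families
#' (mitochondrial `mt-*`, ribosomal `Rps*`/`Rpl*`, oxidative-phosphorylation
#' `Ndufa*`, lncRNA `Gm*`) and a core immediate-early-gene set, so per-cell QC
#' metrics are computable without any annotation resource.
#'
#' @param n_types number of terminal cell types (>= 2).
#' @param n_genes total gene universe size (>= 50).
#' @param n_regions number of labelled anatomical regions (>= 1).
#' @param markers_per_type discrete marker genes planted per type.
#' @param on_fraction target detection frequency of a marker in its home type.
#' @param fold fold difference in marker detection frequency (home vs rest).
#' @param doublet_rate fraction of simulated cells that are doublets; must be
#'   below 0.5.
#' @param depth_ref reference depth (UMIs) at which `on_fraction` is targeted.
#' @param activity `NULL`, or a list with `n_module` (module genes beside the
#'   anchor), `target_r` (scalar or vector of target Pearson correlations with
#'   the anchor) and optionally `anchor_rate` (relative expression of the
#'   anchor, default 2e-3).
#' @param region_tilt concentration of the per-region type composition; larger
#'   values make regions more type-specific. `Inf` assigns disjoint type
#'   blocks to regions.
#' @param seed integer seed; the construction is deterministic given it.
#'
#' @return An object of class `atlas_truth`; see Details for fields.
#' @export
build_ground_truth <- function(n_types, n_genes, n_regions = 1,
                               markers_per_type = 3, on_fraction = 0.9,
                               fold = 20, doublet_rate = 0.05,
                               depth_ref = 5000, activity = NULL,
                               region_tilt = 2, seed = 1) {
  stopifnot(n_types >= 2, n_genes >= 50, n_regions >= 1, markers_per_type >= 1)
  if (doublet_rate < 0 || doublet_rate >= 0.5)
    stop("doublet_rate must lie in [0, 0.5)")
  n_special <- n_types * markers_per_type
  n_module <- if (is.null(activity)) 0L else as.integer(activity$n_module)
  # QC family genes occupy a fixed slice of the universe
  fam <- c(paste0("mt-", seq_len(5)), paste0("Rps", seq_len(5)),
           paste0("Rpl", seq_len(5)), paste0("Ndufa", seq_len(5)),
           paste0("Gm", 10000 + seq_len(5)))
  ieg <- c("Fos", "Junb", "Egr1", "Arc", "Npas4")
  overhead <- n_special + length(fam) + length(ieg) + n_module
  if (overhead >= n_genes)
    stop("marker/module/family genes exceed the gene universe; increase n_genes")

  withr_seed(seed, {
    type_ids <- sprintf("T%02d", seq_len(n_types))
    marker_genes <- character(0)
    marker_table <- do.call(rbind, lapply(seq_len(n_types), function(t) {
      g <- sprintf("Mk%s_%d", type_ids[t], seq_len(markers_per_type))
      data.frame(type = type_ids[t], gene = g,
                 on_fraction = on_fraction, fold = fold,
                 stringsAsFactors = FALSE)
    }))
    marker_genes <- marker_table$gene
    module_genes <- if (n_module > 0) sprintf("Act%03d", seq_len(n_module)) else character(0)
    n_base <- n_genes - length(marker_genes) - length(fam) - length(ieg) - n_module
    base_genes <- sprintf("Gene%04d", seq_len(n_base))
    gene_ids <- c(marker_genes, ieg, module_genes, fam, base_genes)

    # detection-frequency -> rate conversion at the reference depth
    p_on <- -log1p(-on_fraction) / depth_ref
    p_off <- -log1p(-on_fraction / fold) / depth_ref

    # baseline relative expression, shared across types with mild lognormal
    # per-type variation so non-marker genes are not perfectly identical
    base_w <- exp(stats::rnorm(n_base, 0, 0.5))
    # family masses approximate healthy nuclei: mito well under the 1% QC
    # cut, ribo/oxphos/lncRNA at a few percent of counts
    fam_scale <- rep(c(0.1, 1.2, 1.2, 0.8, 0.5), each = 5)
    fam_w <- exp(stats::rnorm(length(fam), 0, 0.3)) * fam_scale
    ieg_w <- exp(stats::rnorm(length(ieg), 0, 0.3))

    anchor_rate <- if (!is.null(activity$anchor_rate)) activity$anchor_rate else 2e-3
    module_rate <- 1e-3

    profiles <- matrix(0, n_types, n_genes, dimnames = list(type_ids, gene_ids))
    for (t in seq_len(n_types)) {
      p <- numeric(n_genes)
      names(p) <- gene_ids
      p[marker_genes] <- p_off
      own <- marker_table$gene[marker_table$type == type_ids[t]]
      p[own] <- p_on
      if (n_module > 0) {
        p["Fos"] <- anchor_rate
        p[module_genes] <- module_rate
      }
      fixed <- sum(p)
      # IEGs without an activity role behave as ordinary baseline genes
      w <- numeric(n_genes); names(w) <- gene_ids
      # per-type baseline variation: real cell types differ broadly, not only
      # in discrete markers, and likelihood-based decomposition relies on it
      w[base_genes] <- base_w * exp(stats::rnorm(n_base, 0, 0.5))
      w[fam] <- fam_w
      w[setdiff(ieg, if (n_module > 0) "Fos" else character(0))] <-
        ieg_w[seq_len(length(ieg) - (n_module > 0))]
      p[names(w)[w > 0]] <- w[w > 0] / sum(w) * (1 - fixed)
      profiles[t, ] <- p
    }

    # activity program: beta solved per target r at the reference depth
    activity_spec <- NULL
    if (n_module > 0) {
      target_r <- rep_len(activity$target_r, n_module)
      beta_anchor <- if (!is.null(activity$beta_anchor)) activity$beta_anchor else 5
      betas <- vapply(seq_len(n_module), function(i) {
        solve_activity_beta(target_r[i], depth_ref, anchor_rate, module_rate,
                            beta_anchor)
      }, numeric(1))
      activity_spec <- list(anchor = "Fos", beta_anchor = beta_anchor,
                            module = data.frame(gene = module_genes,
                                                target_r = target_r,
                                                beta = betas,
                                                stringsAsFactors = FALSE))
    }

    # type hierarchy: balanced binary splits over the ordered type list
    hierarchy <- build_type_hierarchy(type_ids)

    # per-region composition: Dirichlet tilt, or disjoint blocks at Inf
    regions <- sprintf("R%02d", seq_len(n_regions))
    comp <- matrix(0, n_regions, n_types, dimnames = list(regions, type_ids))
    if (is.infinite(region_tilt)) {
      blocks <- split(seq_len(n_types), rep(seq_len(n_regions), length.out = n_types))
      for (r in seq_len(n_regions)) comp[r, blocks[[r]]] <- 1 / length(blocks[[r]])
    } else {
      for (r in seq_len(n_regions)) {
        g <- stats::rgamma(n_types, shape = region_tilt, rate = 1)
        comp[r, ] <- g / sum(g)
      }
    }

    structure(list(
      type_ids = type_ids,
      type_hierarchy = hierarchy,
      type_profiles = profiles,
      marker_table = marker_table,
      type_proportions = stats::setNames(rep(1 / n_types, n_types), type_ids),
      doublet_rate = doublet_rate,
      region_ids = regions,
      region_composition = comp,
      activity_spec = activity_spec,
      gene_ids = gene_ids,
      gene_families = list(mito = "^mt-", ribo = "^Rp[sl]", oxphos = "^Ndufa",
                           lncRNA = "^Gm", ieg = ieg),
      depth_ref = depth_ref,
      seed = seed
    ), class = "atlas_truth")
  })
}

# run expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# balanced recursive bisection of the ordered type list; parent vector format
build_type_hierarchy <- function(type_ids) {
  nodes <- list()
  rec <- function(ids, parent) {
    id <- if (is.null(parent)) "root" else paste0(parent, ".", length(nodes))
    nodes[[length(nodes) + 1]] <<- list(id = id, parent = parent, types = ids)
    if (length(ids) > 1) {
      h <- ceiling(length(ids) / 2)
      rec(ids[seq_len(h)], id)
      rec(ids[-seq_len(h)], id)
    }
  }
  rec(type_ids, NULL)
  nodes
}

# Solve the activity-module scaling factor for a target anchor correlation.
# Model: counts ~ Poisson(n * p * (1 + beta * a)) with a ~ Uniform(0, 1).
# The population correlation between the anchor and a module gene factorizes
# into the two genes' signal-to-total ratios; beta for the module gene is
# found by root search, capped at the attainable maximum.
solve_activity_beta <- function(target_r, depth, p_anchor, p_gene, beta_anchor,
                                beta_max = 200) {
  stn <- function(p, beta) {
    s2 <- (depth * p * beta)^2 / 12
    v <- depth * p * (1 + beta / 2) + s2
    sqrt(s2 / v)
  }
  r_a <- stn(p_anchor, beta_anchor)
  f <- function(beta) r_a * stn(p_gene, beta) - target_r
  if (f(beta_max) < 0) {
    warning("target correlation ", target_r, " unattainable; capping beta")
    return(beta_max)
  }
  stats::uniroot(f, c(1e-6, beta_max), tol = 1e-9)$root
}

#' Simulate single-nucleus expression profiles from a ground truth
#'
#' Each cell draws a region, then a type from that region's composition (or a
#' pair of distinct types mixed 50/50, with probability `doublet_rate`), a
#' sequencing depth from a log-normal with the stated median (sigma = 0.5),
#' and gene counts from a multinomial over the (mixed) profile. Cells carry a
#' latent activity scalar `a ~ Uniform(0,1)` that scales the activity-module
#' genes' rates by `(1 + beta * a)`.
#'
#' @param truth an `atlas_truth` object.
#' @param n_cells number of cells; at least `10 * n_types`.
#' @param depth_median median UMIs per cell.
#' @param seed integer seed.
#' @param n_libraries,n_donors labels distributed round-robin within regions.
#' @return A `cell_profile` object: sparse `counts` (cells x genes,
#'   `dgCMatrix`), `cell_meta` data frame, `gene_ids`.
#' @export
simulate_cells <- function(truth, n_cells, depth_median = 5000, seed = 1,
                           n_libraries = 2, n_donors = 2) {
  stopifnot(inherits(truth, "atlas_truth"))
  n_types <- length(truth$type_ids)
  if (n_cells < 10 * n_types) stop("n_cells must be at least 10 * number of types")
  withr_seed(seed, {
    regions <- sample(truth$region_ids, n_cells, replace = TRUE)
    is_doublet <- stats::runif(n_cells) < truth$doublet_rate
    t1 <- character(n_cells); t2 <- rep(NA_character_, n_cells)
    for (i in seq_len(n_cells)) {
      w <- truth$region_composition[regions[i], ]
      t1[i] <- sample(truth$type_ids, 1, prob = w)
      if (is_doublet[i]) {
        w2 <- w; w2[t1[i]] <- 0
        if (all(w2 == 0)) { is_doublet[i] <- FALSE } else {
          t2[i] <- sample(truth$type_ids, 1, prob = w2)
        }
      }
    }
    depth <- draw_depths(n_cells, depth_median)
    act <- stats::runif(n_cells)

    counts <- matrix(0L, n_cells, length(truth$gene_ids))
    spec <- truth$activity_spec
    for (i in seq_len(n_cells)) {
      p <- truth$type_profiles[t1[i], ]
      if (is_doublet[i]) p <- (p + truth$type_profiles[t2[i], ]) / 2
      if (!is.null(spec)) {
        p[spec$anchor] <- p[spec$anchor] * (1 + spec$beta_anchor * act[i])
        p[spec$module$gene] <- p[spec$module$gene] * (1 + spec$module$beta * act[i])
        p <- p / sum(p)
      }
      counts[i, ] <- stats::rmultinom(1, depth[i], p)[, 1]
    }
    if (n_cells >= 50 * n_types &&
        !all(truth$type_ids %in% t1[!is_doublet]))
      stop("a cell type received no singlet cells despite n_cells >= 50 * types")

    cm <- data.frame(
      cell_id = sprintf("cell%05d", seq_len(n_cells)),
      library_id = paste0(regions, "_L",
                          (seq_len(n_cells) %% n_libraries) + 1),
      donor_id = paste0("D", (seq_len(n_cells) %% n_donors) + 1),
      region = regions,
      truth_type = t1,
      truth_type2 = t2,
      truth_doublet = is_doublet,
      truth_activity = act,
      stringsAsFactors = FALSE
    )
    new_cell_profile(counts, cm, truth$gene_ids)
  })
}

# log-normal depths with exact median parameterization; zero draws resampled
draw_depths <- function(n, median, sigma = 0.5) {
  d <- round(stats::rlnorm(n, meanlog = log(median), sdlog = sigma))
  while (any(d == 0)) d[d == 0] <- round(stats::rlnorm(sum(d == 0), log(median), sigma))
  as.integer(d)
}

new_cell_profile <- function(counts, cell_meta, gene_ids) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  dimnames(counts) <- list(cell_meta$cell_id, gene_ids)
  stopifnot(nrow(cell_meta) == nrow(counts), length(gene_ids) == ncol(counts))
  structure(list(counts = counts, cell_meta = cell_meta, gene_ids = gene_ids),
            class = "cell_profile")
}

#' @export
print.cell_profile <- function(x, ...) {
  cat("cell_profile:", nrow(x$counts), "cells x", ncol(x$counts), "genes;",
      "median depth", stats::median(Matrix::rowSums(x$counts)), "\n")
  invisible(x)
}

#' Simulate spatial capture beads as 1-2 cell-type mixtures
#'
#' Each bead is placed in a region, assigned one type (singlet) or two
#' distinct types with Uniform(0,1) mixture weights (doublet, with probability
#' `doublet_fraction`) drawn from the region's composition, and counts are
#' multinomial at a log-normal depth. Coordinates are uniform in a square
#' field per region (no spatial autocorrelation is modelled).
#'
#' @param truth an `atlas_truth` object.
#' @param n_beads number of beads.
#' @param depth_median median UMIs per bead (spatial beads are shallow).
#' @param doublet_fraction fraction of beads mixing two types.
#' @param seed integer seed.
#' @return A `bead_matrix` object: `counts` (beads x genes), `bead_meta` with
#'   x/y (micrometres), region label, and the truth composition.
#' @export
simulate_beads <- function(truth, n_beads, depth_median = 300,
                           doublet_fraction = 0.2, seed = 1) {
  stopifnot(inherits(truth, "atlas_truth"))
  stopifnot(doublet_fraction >= 0, doublet_fraction <= 1)
  if (any(Matrix::rowSums(truth$region_composition) == 0))
    stop("a region has an empty cell-type composition")
  withr_seed(seed, {
    regions <- sample(truth$region_ids, n_beads, replace = TRUE)
    is_doublet <- stats::runif(n_beads) < doublet_fraction
    t1 <- character(n_beads); t2 <- rep(NA_character_, n_beads)
    w1 <- rep(1, n_beads)
    for (i in seq_len(n_beads)) {
      w <- truth$region_composition[regions[i], ]
      t1[i] <- sample(truth$type_ids, 1, prob = w)
      if (is_doublet[i]) {
        wr <- w; wr[t1[i]] <- 0
        if (all(wr == 0)) { is_doublet[i] <- FALSE } else {
          t2[i] <- sample(truth$type_ids, 1, prob = wr)
          w1[i] <- stats::runif(1)  # Dirichlet(1,1) first weight
        }
      }
    }
    depth <- draw_depths(n_beads, depth_median)
    counts <- matrix(0L, n_beads, length(truth$gene_ids))
    for (i in seq_len(n_beads)) {
      p <- truth$type_profiles[t1[i], ] * w1[i]
      if (is_doublet[i]) p <- p + truth$type_profiles[t2[i], ] * (1 - w1[i])
      counts[i, ] <- stats::rmultinom(1, depth[i], p)[, 1]
    }
    bm <- data.frame(
      bead_id = sprintf("bead%05d", seq_len(n_beads)),
      x = stats::runif(n_beads, 0, 3000),
      y = stats::runif(n_beads, 0, 3000),
      region = regions,
      truth_type = t1, truth_type2 = t2,
      truth_weight1 = ifelse(is_doublet, w1, 1),
      truth_doublet = is_doublet,
      stringsAsFactors = FALSE
    )
    counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
    dimnames(counts) <- list(bm$bead_id, truth$gene_ids)
    structure(list(counts = counts, bead_meta = bm, gene_ids = truth$gene_ids),
              class = "bead_matrix")
  })
}

#' @export
print.bead_matrix <- function(x, ...) {
  cat("bead_matrix:", nrow(x$counts), "beads x", ncol(x$counts), "genes\n")
  invisible(x)
}
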