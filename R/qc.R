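# Nucleus- and cluster-level quality control: hard filters, doublet-marker
# cluster flagging, and the multi-metric "quality network" outlier removal.

#' Per-cell quality metrics
#'
#' Computes the eight per-cell metrics used by the quality network: fraction
#' of counts in oxidative-phosphorylation, mitochondrial, ribosomal-protein,
#' immediate-early and lncRNA gene families, fraction of counts in the cell's
#' own 50 highest-expressed genes, and log2 gene and UMI counts. Families are
#' resolved by regex prefix (or an explicit gene list for the IEGs), so no
#' annotation resource is needed.
#'
#' @param cells a `cell_profile` object.
#' @param families named list with `mito`, `ribo`, `oxphos`, `lncRNA`
#'   (regexes) and `ieg` (gene id vector); defaults match the synthetic
#'   generator's designated prefixes.
#' @return data frame, one row per cell.
#' @export
quality_metrics <- function(cells,
                            families = list(mito = "^mt-", ribo = "^Rp[sl]",
                                            oxphos = "^Ndufa", lncRNA = "^Gm",
                                            ieg = c("Fos", "Junb", "Egr1",
                                                    "Arc", "Npas4"))) {
  counts <- cells$counts
  genes <- colnames(counts)
  depth <- Matrix::rowSums(counts)
  fam_frac <- function(sel) {
    if (!any(sel)) return(rep(0, nrow(counts)))
    Matrix::rowSums(counts[, sel, drop = FALSE]) / depth
  }
  top50 <- apply(as.matrix(counts), 1, function(v) {
    sum(sort(v, decreasing = TRUE)[seq_len(min(50, length(v)))])
  }) / depth
  data.frame(
    cell_id = rownames(counts),
    pct_oxphos = fam_frac(grepl(families$oxphos, genes)),
    pct_mito = fam_frac(grepl(families$mito, genes)),
    pct_ribo = fam_frac(grepl(families$ribo, genes)),
    pct_ieg = fam_frac(genes %in% families$ieg),
    pct_top50 = top50,
    pct_lncRNA = fam_frac(grepl(families$lncRNA, genes)),
    log2_genes = log2(Matrix::rowSums(counts > 0)),
    log2_umis = log2(depth),
    stringsAsFactors = FALSE
  )
}

new_qc_report <- function(retained, removed, reason, extra = list()) {
  stopifnot(length(removed) == length(reason))
  c(list(retained = retained,
         removed = data.frame(cell_id = removed, reason = reason,
                              stringsAsFactors = FALSE)),
    extra)
}

#' Hard per-nucleus filters
#'
#' Removes cells with fewer than `min_umis` total UMIs (`low_umi`) or with a
#' mitochondrial count fraction greater than `max_mito` (`high_mito`); both
#' thresholds are strict inequalities. Reason codes reflect the first rule
#' that fired.
#'
#' @param cells a `cell_profile` object.
#' @param min_umis UMI threshold (default 500; "less than" removes).
#' @param max_mito mitochondrial fraction threshold (default 0.01;
#'   "greater than" removes).
#' @param mito_regex regex identifying the mitochondrial family.
#' @return a QC report list: `retained` ids, `removed` data frame with reason
#'   codes.
#' @export
basic_filter <- function(cells, min_umis = 500, max_mito = 0.01,
                         mito_regex = "^mt-") {
  counts <- cells$counts
  sel <- grepl(mito_regex, colnames(counts))
  if (!any(sel)) stop("mitochondrial gene family matches no genes")
  depth <- Matrix::rowSums(counts)
  mito <- Matrix::rowSums(counts[, sel, drop = FALSE]) / pmax(depth, 1)
  low <- depth < min_umis
  high <- !low & mito > max_mito
  ids <- rownames(counts)
  new_qc_report(ids[!(low | high)],
                ids[low | high],
                ifelse(low[low | high], "low_umi", "high_mito"))
}

#' Subset a cell_profile to a set of cell ids
#' @param cells a `cell_profile`.
#' @param ids cell ids (or logical/integer index) to keep.
#' @return a `cell_profile` restricted to those cells.
#' @export
subset_cells <- function(cells, ids) {
  if (is.character(ids)) ids <- match(ids, cells$cell_meta$cell_id)
  new_cell_profile(as.matrix(cells$counts[ids, , drop = FALSE]),
                   cells$cell_meta[ids, , drop = FALSE], cells$gene_ids)
}

#' Flag putative doublet clusters by cross-class marker co-expression
#'
#' A cluster is flagged when, for some pair of markers of distinct cell
#' classes (e.g. an oligodendrocyte and a glutamatergic marker), both genes
#' are detected in at least `tau_coexp` of the cluster's cells: a genuine
#' cell type expresses at most one of the pair in most cells.
#'
#' @param labels per-cell cluster labels.
#' @param cells a `cell_profile`.
#' @param marker_pairs data frame / matrix with two gene-id columns.
#' @param tau_coexp nonzero-fraction threshold (default 0.5).
#' @return character vector of flagged cluster ids.
#' @export
flag_doublet_clusters <- function(labels, cells, marker_pairs,
                                  tau_coexp = 0.5) {
  marker_pairs <- as.matrix(marker_pairs)
  if (nrow(marker_pairs) == 0) return(character(0))
  unknown <- setdiff(unique(as.vector(marker_pairs)), cells$gene_ids)
  if (length(unknown))
    stop("unknown genes in marker pairs: ", paste(unknown, collapse = ", "))
  counts <- cells$counts
  flagged <- character(0)
  for (cl in sort(unique(labels))) {
    sub <- counts[labels == cl, , drop = FALSE]
    frac <- Matrix::colMeans(sub[, unique(as.vector(marker_pairs)),
                                 drop = FALSE] > 0)
    hit <- apply(marker_pairs, 1, function(pr)
      frac[pr[1]] >= tau_coexp && frac[pr[2]] >= tau_coexp)
    if (any(hit)) flagged <- c(flagged, cl)
  }
  flagged
}

#' Quality-network outlier-cluster removal
#'
#' Separately for neurons and glia, the eight standardized quality metrics
#' are clustered (k=50 Jaccard SNN on Euclidean distance, Leiden at
#' resolution 0.8, modularity objective). A quality cluster is removed when
#' its median exceeds the class-wide 85th percentile in all three of the
#' oxphos, mito and ribo fractions (`quality_cluster`); remaining quality
#' clusters with fewer than `min_cluster` cells are removed
#' (`small_cluster`). Classes with fewer than 30 cells are skipped with a
#' warning.
#'
#' @param cells a `cell_profile` (already basic-filtered).
#' @param metrics data frame from [quality_metrics()] for these cells.
#' @param class_split character vector ("neuron"/"glia" or any labels)
#'   covering all cells.
#' @param resolution Leiden resolution (default 0.8).
#' @param pct percentile defining the outlier reference (default 0.85).
#' @param min_cluster minimum quality-cluster size (default 15).
#' @param k SNN neighbours (default 50).
#' @param seed integer seed.
#' @return QC report list with `retained`, `removed`, and
#'   `cluster_medians` per class.
#' @export
quality_network_qc <- function(cells, metrics, class_split, resolution = 0.8,
                               pct = 0.85, min_cluster = 15, k = 50,
                               seed = 1) {
  stopifnot(length(class_split) == nrow(cells$counts))
  ids <- rownames(cells$counts)
  met_cols <- c("pct_oxphos", "pct_mito", "pct_ribo", "pct_ieg", "pct_top50",
                "pct_lncRNA", "log2_genes", "log2_umis")
  removed <- character(0); reason <- character(0)
  med_list <- list()
  for (cls in unique(class_split)) {
    in_cls <- class_split == cls
    if (sum(in_cls) < 30) {
      warning("class ", cls, " has fewer than 30 cells; network QC skipped")
      next
    }
    m <- as.matrix(metrics[in_cls, met_cols])
    z <- scale(m)
    z[, apply(m, 2, stats::sd) == 0] <- 0
    nn <- knn_indices(z, min(k, sum(in_cls) - 1L), "euclidean")
    g <- snn_graph(nn)
    set.seed(seed)
    part <- igraph::cluster_leiden(g, objective_function = "modularity",
                                   weights = igraph::E(g)$weight,
                                   resolution = resolution, n_iterations = 3)
    memb <- igraph::membership(part)
    ref <- apply(m[, c("pct_oxphos", "pct_mito", "pct_ribo")], 2,
                 stats::quantile, probs = pct)
    meds <- t(vapply(sort(unique(memb)), function(cl)
      apply(m[memb == cl, , drop = FALSE], 2, stats::median),
      numeric(length(met_cols))))
    rownames(meds) <- paste0(cls, "_", sort(unique(memb)))
    med_list[[cls]] <- meds
    for (cl in sort(unique(memb))) {
      sel <- memb == cl
      cm <- meds[paste0(cls, "_", cl), c("pct_oxphos", "pct_mito", "pct_ribo")]
      if (all(cm > ref)) {
        removed <- c(removed, ids[in_cls][sel])
        reason <- c(reason, rep("quality_cluster", sum(sel)))
      } else if (sum(sel) < min_cluster) {
        removed <- c(removed, ids[in_cls][sel])
        reason <- c(reason, rep("small_cluster", sum(sel)))
      }
    }
  }
  new_qc_report(setdiff(ids, removed), removed, reason,
                extra = list(cluster_medians = med_list))
}
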