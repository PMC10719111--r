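# Shared readers/writers and the end-to-end pipeline driver.

#' Write a count matrix with metadata to a directory
#'
#' Sparse MatrixMarket triplet (`matrix.mtx`, genes x cells as customary for
#' the format's consumers is NOT used: rows are cells, mirroring the
#' in-memory orientation) with `features.tsv`, `barcodes.tsv` and a
#' `meta.csv`; round-trips losslessly with [read_counts()].
#'
#' @param x a `cell_profile` or `bead_matrix`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_counts <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(x$counts, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(colnames(x$counts), file.path(dir, "features.tsv"))
  writeLines(rownames(x$counts), file.path(dir, "barcodes.tsv"))
  meta <- if (!is.null(x$cell_meta)) x$cell_meta else x$bead_meta
  utils::write.csv(meta, file.path(dir, "meta.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a count matrix with metadata from a directory
#'
#' Accepts the layout written by [write_counts()]. Values are checked to be
#' non-negative integers and identifiers to be unique; violations raise
#' specific errors.
#'
#' @param dir directory containing `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`, `meta.csv`.
#' @return a `cell_profile` (when the metadata has a `cell_id` column) or
#'   `bead_matrix`.
#' @export
read_counts <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- readLines(file.path(dir, "features.tsv"))
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  meta <- utils::read.csv(file.path(dir, "meta.csv"), stringsAsFactors = FALSE)
  if (length(genes) == 0 || ncol(m) == 0) stop("matrix has 0 genes")
  if (ncol(m) != length(genes))
    stop("dimension mismatch: ", ncol(m), " columns vs ", length(genes), " features")
  if (nrow(m) != length(cells))
    stop("dimension mismatch: ", nrow(m), " rows vs ", length(cells), " barcodes")
  if (nrow(meta) != nrow(m)) stop("metadata row count mismatch")
  if (anyDuplicated(genes)) stop("duplicate feature ids")
  if (anyDuplicated(cells)) stop("duplicate barcodes")
  v <- m@x
  if (any(v < 0) || any(v != round(v))) {
    bad <- which(v != round(v) | v < 0)[1]
    stop("non-integer or negative entry with value ", v[bad])
  }
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(cells, genes)
  if ("cell_id" %in% colnames(meta)) {
    structure(list(counts = m, cell_meta = meta, gene_ids = genes),
              class = "cell_profile")
  } else {
    structure(list(counts = m, bead_meta = meta, gene_ids = genes),
              class = "bead_matrix")
  }
}

#' Default pipeline configuration
#'
#' All stage thresholds default to the published values (500 UMI / 1% mito
#' filters; k = 50 SNN; size-ratio 20; 3 discrete markers at 10%/20%; ridge
#' strengths 0.01/0.001; top-10 pairing; likelihood window 30; confidence
#' 0.3 of max 0.5; 150/20 bead UMIs; 50/100 reference cells; nz = 0.35;
#' coverage 0.95; and so on); the synthetic problem sizes default to 8
#' types, 5,000 cells and 2,000 beads over 2 regions.
#'
#' @param ... overrides for any listed field.
#' @return config list.
#' @export
atlas_config <- function(...) {
  cfg <- list(
    n_types = 8, n_genes = 200, n_regions = 2, n_cells = 5000,
    n_beads = 2000, depth_cells = 5000, depth_beads = 1000,
    doublet_rate = 0.05, bead_doublet_fraction = 0.2,
    markers_per_type = 3, on_fraction = 0.9, fold = 20,
    min_umis = 500, max_mito = 0.01,
    k_snn = 50, max_ratio = 20, n_required = 3,
    min_region = 50, min_total = 100, max_genes = 5000,
    window = 30, confidence_threshold = 0.3,
    tau_on = 0.5, tau_off = 0.1, max_cover = 8,
    coverage_q = 0.95,
    arg_r_min = 0.3, arg_quantile = 0.995, arg_alpha = 0.05,
    sat_k = 19, sat_n_rare = 101, sat_total = 4210212, sat_c_frac = 0.8,
    sat_at = 4388420,
    seed = 1
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

#' Run the synthetic end-to-end pipeline
#'
#' Simulates ground-truth data, applies QC, recursive clustering, per-region
#' spatial decomposition, minimal-marker set cover, regional diversity and
#' saturation, and writes per-stage outputs plus a machine-readable
#' `summary.json` under `out_dir`. Deterministic given `config$seed`.
#'
#' @param config from [atlas_config()].
#' @param out_dir output directory.
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config = atlas_config(), out_dir = tempfile("atlas_run")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- config
  truth <- build_ground_truth(cfg$n_types, cfg$n_genes, cfg$n_regions,
                              markers_per_type = cfg$markers_per_type,
                              on_fraction = cfg$on_fraction, fold = cfg$fold,
                              doublet_rate = cfg$doublet_rate,
                              seed = cfg$seed)
  cells <- simulate_cells(truth, cfg$n_cells, cfg$depth_cells,
                          seed = cfg$seed + 1)
  beads <- simulate_beads(truth, cfg$n_beads, cfg$depth_beads,
                          cfg$bead_doublet_fraction, seed = cfg$seed + 2)

  qc <- basic_filter(cells, cfg$min_umis, cfg$max_mito)
  cells_qc <- subset_cells(cells, qc$retained)

  tree <- iterative_cluster(cells_qc, k = cfg$k_snn, max_ratio = cfg$max_ratio,
                            n_required = cfg$n_required, seed = cfg$seed + 3)
  assignments <- tree$assignments

  refs <- list()
  for (r in truth$region_ids) {
    refs[[r]] <- tryCatch(
      build_region_reference(cells_qc, assignments, r,
                             min_region = cfg$min_region,
                             min_total = cfg$min_total,
                             max_genes = cfg$max_genes),
      error = function(e) NULL)
  }
  mapping <- map_beads(beads, refs, window = cfg$window,
                       threshold = cfg$confidence_threshold)

  # per-leaf detection fractions feed set cover
  leaves <- sort(unique(stats::na.omit(assignments)))
  frac <- do.call(rbind, lapply(leaves, function(l)
    Matrix::colMeans(cells_qc$counts[!is.na(assignments) &
                                       assignments == l, , drop = FALSE] > 0)))
  rownames(frac) <- leaves
  covers <- marker_cover_all(binarize_expression(frac, cfg$tau_on, cfg$tau_off),
                             max_size = cfg$max_cover)

  rtc <- region_type_counts(mapping)
  n95 <- vapply(rownames(rtc), function(r)
    types_for_coverage(rtc[r, ], cfg$coverage_q), 1L)
  sim <- region_similarity(mapping)

  c_req <- required_cells_per_type(cfg$sat_n_rare, cfg$sat_c_frac)
  sspec <- saturation_spec(cfg$sat_k, cfg$sat_n_rare / cfg$sat_total, c_req)
  sat <- success_probability(cfg$sat_at, sspec)

  summary <- list(
    n_cells_in = cfg$n_cells,
    n_cells_qc = length(qc$retained),
    n_leaves = length(tree$leaves),
    n_discarded = length(tree$discarded),
    n_beads_eligible = sum(mapping$beads$eligible),
    n_beads_confident = length(unique(
      mapping$confidence$bead_id[mapping$confidence$confident])),
    n95 = as.list(n95),
    cover_sizes = as.list(table(covers$summary$size[covers$summary$feasible])),
    median_cover_size = stats::median(covers$summary$size, na.rm = TRUE),
    saturation_c = c_req,
    saturation_probability = sat
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  utils::write.csv(data.frame(cell_id = cells_qc$cell_meta$cell_id,
                              leaf = assignments),
                   file.path(out_dir, "leaf_assignments.csv"), row.names = FALSE)
  utils::write.csv(mapping$confidence, file.path(out_dir, "bead_confidence.csv"),
                   row.names = FALSE)
  utils::write.csv(covers$summary, file.path(out_dir, "marker_covers.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(sim), file.path(out_dir, "region_similarity.csv"))
  invisible(summary)
}
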