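#!/usr/bin/env Rscript
# Simulate a ground-truth-labelled synthetic atlas: 8 cell types over 2
# regions, 5,000 nuclei at a median depth of 5,000 UMIs (5% doublets), and
# 2,000 spatial beads at a median depth of 1,000 (20% two-type mixtures).
suppressPackageStartupMessages(library(brainatlas))

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

truth <- build_ground_truth(n_types = 8, n_genes = 200, n_regions = 2,
                            markers_per_type = 3, on_fraction = 0.9,
                            fold = 20, doublet_rate = 0.05, seed = 1)
cells <- simulate_cells(truth, n_cells = 5000, depth_median = 5000, seed = 2)
beads <- simulate_beads(truth, n_beads = 2000, depth_median = 1000,
                        doublet_fraction = 0.2, seed = 3)

write_counts(cells, "results/data/cells")
write_counts(beads, "results/data/beads")

cat("cells:", nrow(cells$counts), "x", ncol(cells$counts),
    "| median depth:", stats::median(Matrix::rowSums(cells$counts)), "\n")
cat("beads:", nrow(beads$counts),
    "| beads >= 150 UMIs:", sum(Matrix::rowSums(beads$counts) >= 150), "\n")
cat("doublet cells:", sum(cells$cell_meta$truth_doublet),
    "| doublet beads:", sum(beads$bead_meta$truth_doublet), "\n")
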