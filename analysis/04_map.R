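#!/usr/bin/env Rscript
# Per-region references with tailored gene lists, then bead decomposition
# with the pair-frequency confidence score.
suppressPackageStartupMessages(library(brainatlas))

cells <- read_counts("results/data/cells_qc")
beads <- read_counts("results/data/beads")
leafs <- utils::read.csv("results/leaf_assignments.csv")
lab <- leafs$leaf[match(cells$cell_meta$cell_id, leafs$cell_id)]

refs <- list()
for (r in sort(unique(beads$bead_meta$region))) {
  refs[[r]] <- tryCatch(build_region_reference(cells, lab, r),
                        error = function(e) NULL)
  cat("region", r, ":", if (is.null(refs[[r]])) "no reference" else
    paste(length(refs[[r]]$types), "reference types"), "\n")
}
mapping <- map_beads(beads, refs)
print(mapping)
n_conf <- length(unique(mapping$confidence$bead_id[mapping$confidence$confident]))
cat("beads with a confident call:", n_conf, "of",
    sum(mapping$beads$eligible), "eligible\n")

utils::write.csv(mapping$beads, "results/bead_pairs.csv", row.names = FALSE)
utils::write.csv(mapping$confidence, "results/bead_confidence.csv",
                 row.names = FALSE)
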