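#!/usr/bin/env Rscript
# Recursive cluster discovery on the QC-passed nuclei, and recovery of the
# planted types.
suppressPackageStartupMessages(library(brainatlas))

cells <- read_counts("results/data/cells_qc")
tree <- iterative_cluster(cells, seed = 7)
print(tree)

sing <- !cells$cell_meta$truth_doublet & !is.na(tree$assignments)
ari <- mclust::adjustedRandIndex(cells$cell_meta$truth_type[sing],
                                 tree$assignments[sing])
cat("leaves:", length(tree$leaves), "| ARI vs truth:", round(ari, 3),
    "| discarded:", length(tree$discarded), "\n")

utils::write.csv(data.frame(cell_id = cells$cell_meta$cell_id,
                            leaf = tree$assignments),
                 "results/leaf_assignments.csv", row.names = FALSE)
reasons <- vapply(tree$nodes, function(nd) nd$reason, "")
utils::write.csv(data.frame(node = names(tree$nodes), reason = reasons,
                            n = vapply(tree$nodes, function(nd) nd$n, 1L)),
                 "results/cluster_nodes.csv", row.names = FALSE)
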