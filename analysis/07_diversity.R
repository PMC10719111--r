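#!/usr/bin/env Rscript
# Regional diversity: types covering 95% of mapped beads, weighted-Jaccard
# region similarity, and a dendrogram neighbourhood around one cluster.
suppressPackageStartupMessages(library(brainatlas))

mapping <- structure(
  list(beads = utils::read.csv("results/bead_pairs.csv"),
       confidence = utils::read.csv("results/bead_confidence.csv"),
       threshold = 0.3),
  class = "bead_mapping")

regions <- sort(unique(mapping$beads$region[mapping$beads$eligible]))
n95 <- vapply(regions, function(r) types_for_coverage(mapping, region = r), 1L)
cat("types for 95% coverage per region:\n"); print(n95)
sim <- region_similarity(mapping)
cat("region similarity:\n"); print(round(sim, 3))

cells <- read_counts("results/data/cells_qc")
leafs <- utils::read.csv("results/leaf_assignments.csv")
lab <- leafs$leaf[match(cells$cell_meta$cell_id, leafs$cell_id)]
genes <- select_variable_genes(cells$counts)
snn <- build_snn(cells$counts, genes, k = 50)
dd <- type_dendrogram(snn, lab)
idx <- sort(unique(stats::na.omit(lab)))[1]
nb <- dendrogram_neighbourhood(dd, idx, cap = 4)
cat("neighbourhood of", idx, "(cap 4):", paste(nb, collapse = ", "), "\n")

utils::write.csv(data.frame(region = regions, n95 = n95),
                 "results/region_n95.csv", row.names = FALSE)
utils::write.csv(as.data.frame(sim), "results/region_similarity.csv")
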