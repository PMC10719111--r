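#!/usr/bin/env Rscript
# Neurochemical identity demonstration on a synthetic per-type panel, and
# the regional inhibitory fraction computed from the bead mapping.
suppressPackageStartupMessages(library(brainatlas))

# synthetic detection-fraction panel over the neurotransmitter rule genes:
# two glutamatergic, two GABAergic, one cholinergic, one dual, two silent
genes <- c("Slc17a7", "Slc17a6", "Slc17a8", "Gad1", "Gad2", "Slc32a1",
           "Slc6a5", "Slc6a9", "Slc18a3", "Chat", "Slc6a3", "Pnmt", "Dbh",
           "Slc6a4", "Tph2")
leaves <- utils::read.csv("results/marker_covers.csv")$type
frac <- matrix(0.02, length(leaves), length(genes),
               dimnames = list(leaves, genes))
half <- seq_len(ceiling(length(leaves) / 2))
frac[half, "Slc17a7"] <- 0.7                          # excitatory half
frac[-half, c("Gad1", "Slc32a1")] <- 0.7              # inhibitory half
frac[length(leaves), c("Slc17a6")] <- 0.5             # one dual type
chem <- assign_neurotransmitters(frac)
print(chem)

mapping <- structure(
  list(beads = utils::read.csv("results/bead_pairs.csv"),
       confidence = utils::read.csv("results/bead_confidence.csv"),
       threshold = 0.3),
  class = "bead_mapping")
ei <- region_ei_fraction(mapping, chem)
print(ei)
utils::write.csv(chem, "results/neurochemistry_synthetic_panel.csv",
                 row.names = FALSE)
utils::write.csv(ei, "results/region_ei.csv", row.names = FALSE)
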