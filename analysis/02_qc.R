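#!/usr/bin/env Rscript
# Per-nucleus quality control: the hard 500-UMI / 1%-mito filters, then the
# eight-metric quality network per class.
suppressPackageStartupMessages(library(brainatlas))

cells <- read_counts("results/data/cells")
qc <- basic_filter(cells)
cat("basic filter removed", nrow(qc$removed), "of", nrow(cells$counts),
    "nuclei\n")
print(table(qc$removed$reason))

cells_qc <- subset_cells(cells, qc$retained)
metrics <- quality_metrics(cells_qc)
# the synthetic world is all neurons; one class network
net <- quality_network_qc(cells_qc, metrics, rep("neuron", nrow(metrics)),
                          seed = 4)
cat("quality network removed", nrow(net$removed), "nuclei\n")

cells_final <- subset_cells(cells_qc, net$retained)
write_counts(cells_final, "results/data/cells_qc")
removed <- rbind(qc$removed, net$removed)
utils::write.csv(removed, "results/qc_removed.csv", row.names = FALSE)
cat("retained", nrow(cells_final$counts), "nuclei\n")
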