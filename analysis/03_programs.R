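#!/usr/bin/env Rscript
# Consensus NMF of the cell data: stability/error across candidate K, then
# the decomposition used downstream (one component above the planted count
# absorbs the shared baseline signal).

source("analysis/00_config.R")

cells <- read_cell_data(file.path(data_dir, "cells"))
cells <- filter_cells_genes(cells, 100L, 100L)
norm <- sweep(as.matrix(cells$counts), 2,
              1e4 / Matrix::colSums(cells$counts), `*`)

ktab <- select_k(t(norm), k_candidates = c(3L, 4L, 6L), n_runs = 5L,
                 seed = 7L)
write.table(ktab, "results/k_selection.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("stability/error across K:\n"); print(ktab, row.names = FALSE)

dec <- run_consensus_nmf(t(norm), k = 4L, n_runs = 8L, seed = 7L)
cat(sprintf("k = 4 consensus: stability %.2f, %d/%d components kept\n",
            dec$stability, dec$n_components_kept, 8L * 4L))
write.table(data.frame(gene = rownames(dec$loadings), dec$loadings),
            "results/loadings.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(cell = rownames(dec$usages), dec$usages),
            "results/usages.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
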