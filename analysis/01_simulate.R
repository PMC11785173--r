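#!/usr/bin/env Rscript
# Simulate the study: ground truth, two burden-test cohorts, Perturb-seq
# style cells, and TF ChIP peaks on a synthetic genome. Everything lands in
# results/data/ in the plain-text interchange formats the loaders read.

source("analysis/00_config.R")

cfg <- study_config()
truth <- simulate_truth(cfg)
write_ground_truth_json(truth, file.path(data_dir, "truth.json"))

burden1 <- simulate_burden_stats(truth, cfg, cohort_seed = 1001L)
burden2 <- simulate_burden_stats(truth, cfg, cohort_seed = 2002L)
write_burden_tsv(burden1, file.path(data_dir, "burden_cohort1.tsv"))
write_burden_tsv(burden2, file.path(data_dir, "burden_cohort2.tsv"))

cells <- simulate_cells(truth, cfg)
write_cell_data(cells, file.path(data_dir, "cells"))

chip <- simulate_chip_peaks(truth, peaks_per_target = 2L,
                            strength_range = c(5, 30), seed = 11L,
                            background_tfs = "TFbg")
write_narrowpeak(chip$peaks, file.path(data_dir, "peaks.narrowPeak"))
write_tss_bed(chip$tss, file.path(data_dir, "tss.bed"))

cat(sprintf("simulated %d genes, %d cells (%d batches), %d TF peak rows\n",
            cfg$n_genes, ncol(cells$counts), cfg$n_batches,
            nrow(chip$peaks)))
cat(sprintf("planted trait weights: regulator path %s; content %s\n",
            paste(cfg$regulator_path_weight_per_program, collapse = "/"),
            paste(cfg$content_weight_per_program, collapse = "/")))
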