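test_that("ground truth is deterministic and respects planted structure", {
  cfg <- tiny_config()
  t1 <- simulate_truth(cfg)
  t2 <- simulate_truth(cfg)
  expect_identical(t1, t2)

  expect_true(all(t1$loadings >= 0))
  # regulators and members are disjoint within and across programs
  expect_length(intersect(names(t1$regulators), names(t1$program_membership)), 0)
  expect_equal(sum(t1$regulator_effects != 0),
               cfg$n_programs * cfg$n_regulators_per_program)
  expect_true(all(t1$shet > 0 & t1$shet < 1))
})

test_that("noise-free single-program truth reproduces the regulator path exactly", {
  cfg <- sim_config(n_genes = 40L, n_programs = 1L,
                    n_regulators_per_program = 10L,
                    n_member_genes_per_program = 5L,
                    regulator_path_weight_per_program = 1,
                    content_weight_per_program = 0,
                    trait_noise_sd = 0, seed = 2L)
  tr <- simulate_truth(cfg)
  expect_equal(unname(tr$gamma_true), unname(tr$regulator_effects[, 1]))
})

test_that("shet couples to |gamma| when requested", {
  cfg <- sim_config(n_genes = 500L, n_programs = 2L,
                    n_regulators_per_program = 40L,
                    n_member_genes_per_program = 40L,
                    shet_gamma_coupling = 0.6, seed = 9L)
  tr <- simulate_truth(cfg)
  expect_gt(cor(tr$shet, abs(tr$gamma_true)), 0)
})

test_that("infeasible gene budgets are rejected", {
  expect_error(sim_config(n_genes = 10L, n_programs = 2L,
                          n_regulators_per_program = 4L,
                          n_member_genes_per_program = 4L),
               "budget")
  expect_error(sim_config(se_range = c(0.3, 0.1)), "se_range")
})

test_that("burden stats: noise scale, cohort independence, shet-monotone SE", {
  cfg <- tiny_config()
  tr <- simulate_truth(cfg)
  b1 <- simulate_burden_stats(tr, cfg, cohort_seed = 1L)
  b2 <- simulate_burden_stats(tr, cfg, cohort_seed = 2L)
  # same truth, independent noise
  expect_false(any(b1$gamma_hat == b2$gamma_hat))
  expect_identical(b1$se, b2$se)
  expect_identical(b1$shet, b2$shet)
  # SE increases with shet
  expect_true(all(diff(b1$se[order(b1$shet)]) >= 0))

  # vanishing noise limit
  cfg0 <- tiny_config(se_range = c(1e-9, 2e-9))
  tr0 <- simulate_truth(cfg0)
  b0 <- simulate_burden_stats(tr0, cfg0, 3L)
  expect_equal(b0$gamma_hat, unname(tr0$gamma_true), tolerance = 1e-6)

  # Monte-Carlo: empirical sd of gamma_hat - gamma matches the written SE
  cfgN <- sim_config(n_genes = 10000L, n_programs = 1L,
                     n_regulators_per_program = 1L,
                     n_member_genes_per_program = 1L,
                     se_range = c(0.2, 0.200001), seed = 4L)
  trN <- simulate_truth(cfgN)
  bN <- simulate_burden_stats(trN, cfgN, 5L)
  resid_sd <- sd(bN$gamma_hat - trN$gamma_true)
  expect_gt(resid_sd, 0.19)
  expect_lt(resid_sd, 0.21)
})

test_that("cells carry one perturbation each; depth and batches behave", {
  cfg <- tiny_config()
  tr <- simulate_truth(cfg)
  cd <- simulate_cells(tr, cfg)
  expect_equal(ncol(cd$counts), nrow(cd$cells))
  expect_setequal(unique(cd$cells$perturbation),
                  c(tr$genes, "non-targeting"))
  expect_true(all(cd$counts@x >= 0))
  expect_equal(length(unique(cd$cells$batch)), cfg$n_batches)
  # zero depth -> all-zero counts
  cfg0 <- tiny_config(mean_depth = 0)
  cd0 <- simulate_cells(simulate_truth(cfg0), cfg0)
  expect_equal(sum(cd0$counts), 0)
})

test_that("null regulatory effects leave perturbed cells exchangeable", {
  cfg <- sim_config(n_genes = 30L, n_programs = 1L,
                    n_regulators_per_program = 5L,
                    n_member_genes_per_program = 10L,
                    regulator_effect_scale = 1, n_cells_per_perturbation = 60L,
                    n_nontargeting_cells = 300L, mean_depth = 3000, seed = 8L)
  tr <- simulate_truth(cfg)
  tr$regulator_effects[] <- 0
  cd <- simulate_cells(tr, cfg)
  logm <- lognormalize(cd)
  nt <- cd$cells$perturbation == "non-targeting"
  pert <- cd$cells$perturbation == tr$genes[1]
  ks_p <- vapply(seq_len(nrow(logm)), function(g)
    suppressWarnings(ks.test(logm[g, pert], logm[g, nt])$p.value), 0)
  expect_gte(mean(ks_p > 0.01), 0.95)
})

test_that("knocking down a negative-shift regulator lowers its program usage", {
  cfg <- sim_config(n_genes = 30L, n_programs = 1L,
                    n_regulators_per_program = 5L,
                    n_member_genes_per_program = 10L,
                    n_cells_per_perturbation = 80L,
                    n_nontargeting_cells = 300L, mean_depth = 3000, seed = 8L)
  tr <- simulate_truth(cfg)
  reg <- names(tr$regulators)[1]
  tr$regulator_effects[reg, 1] <- -0.8        # knockdown suppresses program
  cd <- simulate_cells(tr, cfg)
  # program members' summed expression proxies usage
  members <- names(tr$program_membership)
  msum <- Matrix::colSums(cd$counts[members, ]) /
    pmax(Matrix::colSums(cd$counts), 1)
  expect_lt(mean(msum[cd$cells$perturbation == reg]),
            mean(msum[cd$cells$perturbation == "non-targeting"]))
})

test_that("chip peaks land on target TSSs and obey strength ranges", {
  cfg <- tiny_config()
  tr <- simulate_truth(cfg)
  pk <- simulate_chip_peaks(tr, peaks_per_target = 1L,
                            strength_range = c(5, 5), window_bp = 0L,
                            n_background = 0L)
  tss_of <- setNames(pk$tss$start, pk$tss$gene)
  for (tf in names(tr$tf_assignments)) {
    p <- tr$tf_assignments[[tf]]
    targets <- names(tr$program_membership)[tr$program_membership == p]
    sub <- pk$peaks[pk$peaks$tf == tf, ]
    centers <- sub$start + sub$summit_offset
    expect_setequal(centers, unname(tss_of[targets]))
  }
  expect_true(all(pk$peaks$strength == 5))
  tr_empty <- tr; tr_empty$tf_assignments <- setNames(integer(), character())
  expect_error(simulate_chip_peaks(tr_empty), "empty")
})

test_that("writers round-trip and are byte-identical across reruns", {
  cfg <- tiny_config()
  tr <- simulate_truth(cfg)
  bs <- simulate_burden_stats(tr, cfg, 7L)
  cd <- simulate_cells(tr, cfg)
  pk <- simulate_chip_peaks(tr, seed = 3L)

  d <- withr::local_tempdir()
  f_b <- file.path(d, "burden.tsv")
  write_burden_tsv(bs, f_b)
  expect_equal(read_burden_tsv(f_b)$gamma_hat, bs$gamma_hat, tolerance = 1e-12)

  write_cell_data(cd, file.path(d, "cells"))
  cd2 <- read_cell_data(file.path(d, "cells"))
  expect_equal(as.matrix(cd2$counts), as.matrix(cd$counts))
  expect_equal(cd2$cells$perturbation, cd$cells$perturbation)

  f_np <- file.path(d, "peaks.narrowPeak")
  write_narrowpeak(pk$peaks, f_np)
  pk2 <- read_narrowpeak(f_np)
  expect_equal(pk2$strength, pk$peaks$strength, tolerance = 1e-12)
  expect_equal(pk2$start, pk$peaks$start)

  f_bed <- file.path(d, "tss.bed")
  write_tss_bed(pk$tss, f_bed)
  expect_equal(read_tss_bed(f_bed)$start, pk$tss$start)

  f_j <- file.path(d, "truth.json")
  write_ground_truth_json(tr, f_j)
  tr2 <- read_ground_truth_json(f_j)
  expect_equal(tr2$loadings, tr$loadings, tolerance = 1e-12)
  expect_equal(tr2$gamma_true, tr$gamma_true, tolerance = 1e-12)
  expect_equal(tr2$program_membership, tr$program_membership)

  # identical seed -> identical bytes
  f_b2 <- file.path(d, "burden2.tsv")
  write_burden_tsv(simulate_burden_stats(simulate_truth(cfg), cfg, 7L), f_b2)
  expect_identical(readLines(f_b), readLines(f_b2))
})
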