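test_that("best-subset selection matches brute-force enumeration at K = 8", {
  set.seed(55)
  n <- 200
  genes <- sprintf("g%03d", 1:n)
  B <- matrix(rnorm(n * 8), n, 8, dimnames = list(genes, paste0("P", 1:8)))
  shet <- setNames(rbeta(n, 2, 5), genes)
  gamma <- setNames(0.5 * B[, 2] - 0.3 * B[, 5] + 0.2 * B[, 7] +
                      0.3 * shet + rnorm(n, 0, 0.1), genes)
  res <- select_regulator_programs(gamma, B, shet, max_subset = 4)
  oracle <- oracle_best_subsets(gamma, B, shet, 4)
  for (s in 0:4) {
    expect_equal(res$r2_path$r2[res$r2_path$s == s],
                 oracle[[as.character(s)]]$r2, tolerance = 1e-10)
    if (s > 0)
      expect_equal(sort(as.integer(strsplit(
        res$r2_path$subset[res$r2_path$s == s], "+", fixed = TRUE)[[1]])),
        sort(oracle[[as.character(s)]]$subset))
  }
  expect_setequal(res$chosen, c(2, 5, 7))
})

test_that("noise-free single-program signal is selected with the right sign", {
  sc <- planted_scenario(K = 3, w = c(0.7, 0, 0), content = c(0, 0, 0),
                         gamma_noise = 1e-6, seed = 7L)
  res <- select_regulator_programs(sc$gamma, sc$B, sc$shet, max_subset = 3)
  expect_equal(res$chosen_size, 1L)
  expect_equal(res$chosen, 1L)
  expect_gt(res$weights[["P1"]], 0)
  expect_equal(res$weights[["P1"]], 0.7, tolerance = 0.05)
  # max_subset = 0: shet-only model
  res0 <- select_regulator_programs(sc$gamma, sc$B, sc$shet, max_subset = 0)
  expect_length(res0$chosen, 0)
  # budget guard
  big_B <- matrix(rnorm(200 * 30), 200, 30,
                  dimnames = list(sc$genes[1:200], paste0("Q", 1:30)))
  expect_error(select_regulator_programs(sc$gamma[1:200], big_B,
                                         sc$shet[1:200], max_subset = 5,
                                         model_budget = 1000), "budget")
})

test_that("null gamma keeps the R2 path flat around the shet baseline", {
  sc <- planted_scenario(seed = 9L)
  set.seed(1)
  g_null <- setNames(rnorm(length(sc$gamma), 0, 0.2), sc$genes)
  res <- select_regulator_programs(g_null, sc$B, sc$shet, max_subset = 3)
  expect_lt(max(res$r2_path$r2) - res$baseline_r2, 0.05)
})

test_that("content programs rank the planted program first", {
  sc <- planted_scenario(content = c(0.4, 0, 0), w = c(0, 0, 0), seed = 11L)
  tab <- select_content_programs(sc$gamma, sc$loadings, sc$shet,
                                 n_top = 40, n_perm = 500, seed = 2)
  expect_equal(tab$program[1], 1)
  expect_equal(tab$content_sign[1], 1)
  # deterministic under the same seed
  tab2 <- select_content_programs(sc$gamma, sc$loadings, sc$shet,
                                  n_top = 40, n_perm = 500, seed = 2)
  expect_identical(tab, tab2)
  # keep = 0 selects nothing
  tab0 <- select_content_programs(sc$gamma, sc$loadings, sc$shet,
                                  n_top = 40, n_perm = 200,
                                  n_programs_keep = 0, seed = 2)
  expect_false(any(tab0$chosen))
  # the fast path agrees on the ranking for a strong plant
  tabm <- select_content_programs(sc$gamma, sc$loadings, sc$shet,
                                  n_top = 40, method = "mwu")
  expect_equal(tabm$program[1], 1)
})

test_that("gene sign assignment follows paths, cancellation and precedence", {
  weights <- c(P1 = 0.5, P2 = -0.4)
  eff <- data.frame(
    perturbed_gene = c("gR", "gC", "gC", "gM", "gM", "gM"),
    response = c("P1", "P1", "P2", "P1", "P2", "P3"),
    beta = c(0.8, 0.4, 0.5, 0.6, -0.5, 1),
    se = 0.1, p_value = 1e-5, fdr = 1e-4, self = FALSE,
    stringsAsFactors = FALSE)
  L <- matrix(0, 3, 3, dimnames = list(c("gR", "gC", "gX"),
                                       paste0("P", 1:3)))
  L["gX", 3] <- 1
  content <- data.frame(program = 3, mean_gamma = -0.2, p = 1e-4,
                        content_sign = -1, chosen = TRUE)
  asg <- assign_gene_signs(weights, eff, L, content, n_top = 1,
                           fdr = 0.05)
  # single path: sign(w_p * beta)
  expect_equal(asg$predicted_sign[asg$gene == "gR"], 1)
  # cancellation: 0.5*0.4 - 0.4*0.5 = 0 -> unassigned
  expect_true(is.na(asg$predicted_sign[asg$gene == "gC"]))
  # concordant multi-path regulator: 0.5*0.6 + (-0.4)*(-0.5) both positive
  expect_equal(asg$predicted_sign[asg$gene == "gM"], 1)
  expect_equal(asg$total_effect[asg$gene == "gM"],
               0.5 * 0.6 + (-0.4) * (-0.5), tolerance = 1e-12)
  # content gene takes the program sign
  expect_equal(asg$predicted_sign[asg$gene == "gX"], -1)
  expect_equal(asg$role[asg$gene == "gX"], "program_gene")
})

test_that("program-gene sign takes precedence over the regulator sign", {
  weights <- c(P1 = 0.5)
  eff <- data.frame(perturbed_gene = "gD", response = "P1", beta = 1,
                    se = 0.1, p_value = 1e-6, fdr = 1e-5, self = FALSE)
  L <- matrix(c(1, 0), 2, 1, dimnames = list(c("gD", "gZ"), "P1"))
  content <- data.frame(program = 1, mean_gamma = -0.3, p = 1e-3,
                        content_sign = -1, chosen = TRUE)
  asg <- assign_gene_signs(weights, eff, L, content, n_top = 1)
  row <- asg[asg$gene == "gD", ]
  expect_equal(row$role, "program_gene")
  expect_equal(row$predicted_sign, -1)       # not the regulator's +1
})

test_that("LOOCV enriches correct predictions among high-effect genes", {
  sc <- planted_scenario(gamma_noise = 0.01, seed = 21L)
  res <- loocv_evaluate(sc$gamma, sc$B, sc$shet, sc$effects, sc$loadings,
                        s_reg = 3, n_keep = 3, n_top = 40,
                        high_threshold = 0.3, low_threshold = 0.05)
  expect_gt(res$odds_ratio, 1)
  expect_lt(res$fisher_p, 0.05)
  high <- res$predictions[res$predictions$stratum == "high", ]
  expect_gt(mean(high$correct), 0.8)
  expect_error(
    loocv_evaluate(sc$gamma, sc$B, sc$shet, sc$effects, sc$loadings,
                   s_reg = 3, n_keep = 3, n_top = 40,
                   high_threshold = max(abs(sc$gamma)) + 1), "high_threshold")
})

test_that("label permutations separate planted signal from null", {
  sc <- planted_scenario(gamma_noise = 0.01, seed = 23L)
  res <- permutation_test(sc$gamma, sc$B, sc$shet, sc$effects, sc$loadings,
                          s_reg = 3, n_keep = 3, n_top = 40,
                          high_threshold = 0.3, n_perm = 200, seed = 5,
                          n_perm_content = 300)
  expect_lte(res$permutation_p, 0.01)
  expect_gte(res$permutation_p, 1 / 201)
  expect_length(res$perm_fisher_p, 200)
  expect_error(permutation_test(sc$gamma, sc$B, sc$shet, sc$effects,
                                sc$loadings, 3, 3, n_perm = 0), "n_perm")
})

test_that("cross-validated variance explained separates true sets from noise", {
  sc <- planted_scenario(gamma_noise = 1e-4, content = c(0, 0, 0),
                         seed = 31L)
  sets <- list(all3 = 1:3, p1 = 1L, p2 = 2L, empty = integer())
  cv <- crossval_variance_explained(sc$gamma, sc$B, sc$shet, sets,
                                    n_splits = 20, seed = 3)
  expect_gt(cv$mean_test_r2[cv$set == "all3"], 0.95)
  expect_gt(cv$mean_test_r2[cv$set == "all3"],
            max(cv$mean_test_r2[cv$set %in% c("p1", "p2")]))
  # pure-noise gamma explains nothing out of sample
  set.seed(4)
  g_null <- setNames(rnorm(length(sc$gamma), 0, 1), sc$genes)
  cv_null <- crossval_variance_explained(g_null, sc$B, sc$shet,
                                         list(all3 = 1:3),
                                         n_splits = 20, seed = 3)
  expect_lt(cv_null$mean_test_r2, 0.02)
  expect_error(crossval_variance_explained(sc$gamma, sc$B, sc$shet,
                                           sets, split = 1), "split")
})

test_that("graphs keep only concordant high-effect genes and round-trip", {
  sc <- planted_scenario(gamma_noise = 0.01, seed = 41L)
  sel <- select_regulator_programs(sc$gamma, sc$B, sc$shet, max_subset = 3)
  content <- select_content_programs(sc$gamma, sc$loadings, sc$shet,
                                     n_top = 40, n_perm = 500, seed = 2,
                                     n_programs_keep = 3)
  asg <- assign_gene_signs(sel$weights, sc$effects, sc$loadings, content,
                           n_top = 40)
  gr <- build_graph("traitX", sc$gamma, asg, sel$weights, content,
                    sc$effects, high_threshold = 0.3)
  # no discordant gene survives
  kept <- gr$gene_assignments
  expect_true(all(kept$predicted_sign == sign(sc$gamma[kept$gene])))
  expect_true(all(abs(sc$gamma[kept$gene]) > 0.3))
  expect_true(all(gr$edges$kind %in% c("regulates", "member_of", "affects")))

  d <- withr::local_tempdir()
  f1 <- file.path(d, "graph.json"); f2 <- file.path(d, "graph2.json")
  write_trait_graph_json(gr, f1)
  gr2 <- read_trait_graph_json(f1)
  write_trait_graph_json(gr2, f2)
  expect_identical(readLines(f1), readLines(f2))  # lossless round trip
  expect_equal(gr2$regulator_programs$weight, gr$regulator_programs$weight,
               tolerance = 1e-12)
  write_graph_edges_tsv(gr, file.path(d, "edges.tsv"))
  ed <- read.table(file.path(d, "edges.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(ed), nrow(gr$edges))
})

test_that("opposite trait weights on a shared program flip regulator signs", {
  sc <- planted_scenario(K = 2, w = c(0.6, 0.3), content = c(0, 0),
                         gamma_noise = 0.01, seed = 51L)
  gamma_b <- setNames(drop(sc$B_true %*% c(-0.6, 0.3)), sc$genes) +
    rnorm(length(sc$genes), 0, 0.01)
  fit_a <- select_regulator_programs(sc$gamma, sc$B, sc$shet, max_subset = 2)
  fit_b <- select_regulator_programs(gamma_b, sc$B, sc$shet, max_subset = 2)
  empty_content <- data.frame(program = integer(), mean_gamma = numeric(),
                              p = numeric(), content_sign = numeric(),
                              chosen = logical())
  asg_a <- assign_gene_signs(fit_a$weights, sc$effects, sc$loadings,
                             empty_content)
  asg_b <- assign_gene_signs(fit_b$weights, sc$effects, sc$loadings,
                             empty_content)
  p1_only <- intersect(sc$regulators[[1]], asg_a$gene)
  p1_only <- intersect(p1_only, asg_b$gene)
  sa <- setNames(asg_a$predicted_sign, asg_a$gene)[p1_only]
  sb <- setNames(asg_b$predicted_sign, asg_b$gene)[p1_only]
  ok <- !is.na(sa) & !is.na(sb)
  expect_gt(mean(sa[ok] == -sb[ok]), 0.9)
})
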