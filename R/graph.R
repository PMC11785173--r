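#' @title Five-step construction of the gene-to-program-to-trait graph
#' @description
#' STEP 1 selects programs whose regulators jointly explain the gene-level
#' trait effects (exhaustive best-subset regression of gamma on the
#' perturbation effects beta with shet always included). STEP 2 selects
#' programs whose content genes carry trait signal (constraint-matched
#' permutation ranking of program burden effects). STEP 3 assigns each gene
#' a predicted sign: regulators through `sum_p w_p * beta_{x->p}` over the
#' selected programs they significantly regulate, content genes through the
#' sign of their program's mean gamma, with the content sign taking
#' precedence for genes in both roles. STEP 4 validates by leave-one-out
#' cross-validation (Fisher enrichment of correct predictions among
#' high-effect genes) and by gene-label permutation. STEP 5 emits the graph
#' restricted to high-effect genes whose predicted sign matches the data.
#' @name trait-graph
NULL

# Align gamma/shet/effect-matrix on a shared gene set and build the design
# X = [intercept | beta_1..beta_K | shet] with crossproducts for fast
# best-subset R^2 evaluation.
subset_engine <- function(gamma, effects_by_program, shet) {
  genes <- Reduce(intersect, list(names(gamma), rownames(effects_by_program),
                                  names(shet)))
  y <- gamma[genes]
  B <- effects_by_program[genes, , drop = FALSE]
  X <- cbind(1, B, shet[genes])
  K <- ncol(B)
  list(genes = genes, y = y, X = X, K = K,
       G = crossprod(X), c = crossprod(X, y), yty = sum(y * y),
       n = length(y), ybar = mean(y))
}

# R^2 and coefficients of the model using design columns `cols` (must
# include the intercept column 1); returns NULL on a singular subsystem.
subset_fit <- function(eng, cols, G = eng$G, c_ = eng$c, yty = eng$yty,
                       n = eng$n) {
  b <- try(solve(G[cols, cols, drop = FALSE], c_[cols]), silent = TRUE)
  if (inherits(b, "try-error")) return(NULL)
  rss <- yty - sum(b * c_[cols])
  ybar <- c_[1] / n                       # X[,1] is the intercept
  tss <- yty - n * ybar^2
  list(r2 = 1 - rss / tss, coef = b)
}

#' STEP 1: best-subset selection of regulator-associated programs
#'
#' For each subset size `s <= max_subset`, exhaustively searches program
#' subsets maximising the R^2 of `gamma ~ beta(subset) + shet` (intercept
#' and shet always included). The final size is the largest s whose R^2 gain
#' over s-1 is at least `gain_frac` of the total gain from the shet-only
#' baseline to the `max_subset` optimum — an explicit, configurable version
#' of choosing by inspection of the variance-explained path.
#'
#' @param gamma named per-gene effect sizes.
#' @param effects_by_program gene x K matrix of perturbation effects on
#'   program usages.
#' @param shet named per-gene constraint.
#' @param max_subset largest subset size searched.
#' @param size_rule `"cv"` (default) picks the size maximising the mean
#'   out-of-sample R^2 over repeated 80/20 gene splits — robust when the
#'   per-program effect estimates are collinear mixtures, where in-sample
#'   gains concentrate on the first subset; `"gain"` uses the in-sample
#'   elbow: the largest size whose R^2 gain over the previous size is at
#'   least `gain_frac` of the total gain.
#' @param gain_frac R^2-gain fraction defining the elbow for
#'   `size_rule = "gain"`.
#' @param model_budget maximum number of candidate models enumerated.
#' @param n_splits,cv_seed splits and seed for `size_rule = "cv"`.
#' @return list: `chosen` (program indices), `weights` (named w_p from the
#'   joint OLS fit), `chosen_size`, `r2_path` (data.frame `s`, `r2`,
#'   `subset`, and `cv_r2` under the CV rule), `baseline_r2` (shet-only).
#' @export
select_regulator_programs <- function(gamma, effects_by_program, shet,
                                      max_subset = 5L,
                                      size_rule = c("cv", "gain"),
                                      gain_frac = 0.1,
                                      model_budget = 2e6,
                                      n_splits = 40L, cv_seed = 1L) {
  size_rule <- match.arg(size_rule)
  eng <- subset_engine(gamma, effects_by_program, shet)
  K <- eng$K
  max_subset <- min(max_subset, K)
  n_models <- sum(vapply(seq_len(max_subset), function(s) choose(K, s), 0))
  if (n_models > model_budget)
    stopf("%g candidate models exceed the budget of %g; lower max_subset",
          n_models, model_budget)
  shet_col <- K + 2L
  base <- subset_fit(eng, c(1L, shet_col))
  path <- data.frame(s = 0L, r2 = base$r2, subset = "", stringsAsFactors = FALSE)
  best <- list(`0` = list(subset = integer(), fit = base))
  for (s in seq_len(max_subset)) {
    combos <- utils::combn(K, s, simplify = FALSE)
    best_fit <- NULL; best_sub <- NULL
    for (sub in combos) {
      f <- subset_fit(eng, c(1L, 1L + sub, shet_col))
      if (is.null(f)) next
      if (is.null(best_fit) || f$r2 > best_fit$r2) {
        best_fit <- f; best_sub <- sub
      }
    }
    if (is.null(best_fit)) stopf("all size-%d subsets were singular", s)
    best[[as.character(s)]] <- list(subset = best_sub, fit = best_fit)
    path <- rbind(path, data.frame(s = s, r2 = best_fit$r2,
                                   subset = paste(best_sub, collapse = "+")))
  }
  if (size_rule == "gain") {
    total_gain <- path$r2[nrow(path)] - base$r2
    chosen_size <- 0L
    for (s in seq_len(max_subset)) {
      gain <- path$r2[s + 1L] - path$r2[s]
      if (total_gain > 0 && gain >= gain_frac * total_gain) chosen_size <- s
      else break
    }
  } else {
    sets <- lapply(0:max_subset, function(s) best[[as.character(s)]]$subset)
    names(sets) <- as.character(0:max_subset)
    cv <- crossval_variance_explained(gamma, effects_by_program, shet, sets,
                                      n_splits = n_splits, seed = cv_seed)
    path$cv_r2 <- cv$mean_test_r2[match(as.character(path$s), cv$set)]
    best_cv <- max(path$cv_r2)
    chosen_size <- min(path$s[path$cv_r2 >= best_cv - 1e-3])
  }
  ch <- best[[as.character(chosen_size)]]
  weights <- if (chosen_size > 0L)
    stats::setNames(ch$fit$coef[seq_len(chosen_size) + 1L],
                    colnames(effects_by_program)[ch$subset])
  else stats::setNames(numeric(0), character(0))
  list(chosen = ch$subset, weights = weights, chosen_size = chosen_size,
       r2_path = path, baseline_r2 = base$r2)
}

# Mann-Whitney ranking statistic for program content: two-sided p comparing
# gamma of the top-loading genes against all other genes (the fast path).
content_mwu_p <- function(gamma, loadings, program, n_top) {
  top <- top_loading_genes(loadings, program, n_top)
  rest <- setdiff(rownames(loadings), top)
  g_top <- gamma[top]; g_rest <- gamma[rest]
  if (stats::sd(c(g_top, g_rest)) == 0) return(1)
  stats::wilcox.test(g_top, g_rest, exact = FALSE)$p.value
}

#' STEP 2: selection of content-associated programs
#'
#' Ranks programs by the significance of their program burden effect —
#' either the constraint-matched permutation p ([program_burden_effect()],
#' the default) or the Mann-Whitney fast path — and keeps the top
#' `n_programs_keep`, each with the sign of its top genes' mean gamma.
#' `n_programs_keep = NULL` keeps the Bonferroni-significant count.
#'
#' @inheritParams program_burden_effect
#' @param n_programs_keep how many programs to keep (`NULL` = Bonferroni).
#' @param method `"permutation"` (shet-matched) or `"mwu"` (fast path).
#' @return data.frame per program sorted by rank: `program`, `mean_gamma`,
#'   `p`, `content_sign`, `chosen`.
#' @export
select_content_programs <- function(gamma, loadings, shet, n_top = 200L,
                                    n_perm = 10000L, n_programs_keep = NULL,
                                    seed = 7L,
                                    method = c("permutation", "mwu")) {
  method <- match.arg(method)
  K <- ncol(loadings)
  if (!is.null(n_programs_keep) && n_programs_keep > K)
    stopf("n_programs_keep exceeds the number of programs")
  gamma <- gamma[rownames(loadings)]
  rows <- lapply(seq_len(K), function(p) {
    top <- top_loading_genes(loadings, p, n_top)
    mg <- mean(gamma[top])
    pv <- if (method == "permutation")
      program_burden_effect(gamma, loadings, shet, p, n_top, n_perm,
                            seed + p)[["p"]]
    else content_mwu_p(gamma, loadings, p, n_top)
    data.frame(program = p, mean_gamma = mg, p = pv,
               content_sign = if (mg >= 0) 1 else -1)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$program), , drop = FALSE]
  keep <- if (is.null(n_programs_keep)) sum(out$p < 0.05 / K)
  else n_programs_keep
  out$chosen <- seq_len(nrow(out)) <= keep
  rownames(out) <- NULL
  out
}

#' STEP 3: per-gene predicted signs
#'
#' Regulators are genes with FDR < `fdr` on at least one selected regulator
#' program; their total effect is `sum_p w_p * beta_{x->p}` over those
#' programs, and the predicted sign is its sign (unassigned when the paths
#' cancel to within `tol`). Content genes are the top `n_top` loading genes
#' of each selected content program and take that program's content sign;
#' for a gene in several selected content programs the most significant
#' program wins, and the content sign overrides the regulator sign for
#' dual-role genes.
#'
#' @param weights named w_p vector (names = program column names).
#' @param effects `PerturbEffectTable` with per-response FDR on programs.
#' @param loadings gene x K loadings (colnames matching effect responses).
#' @param content data.frame from [select_content_programs()].
#' @param n_top content-gene count per program (default 200).
#' @param fdr regulator significance threshold.
#' @param tol cancellation tolerance for unassigned regulator signs.
#' @return data.frame: `gene`, `role` (`"regulator"`/`"program_gene"`),
#'   `programs` (`+`-joined), `predicted_sign` (+1/-1/NA), `total_effect`.
#' @export
assign_gene_signs <- function(weights, effects, loadings, content,
                              n_top = 200L, fdr = 0.05, tol = 1e-12) {
  prog_names <- colnames(loadings)
  assign <- list()
  if (length(weights) > 0L) {
    sel <- names(weights)
    sig <- effects[effects$response %in% sel & effects$fdr < fdr &
                     !effects$self, , drop = FALSE]
    for (g in unique(sig$perturbed_gene)) {
      rows <- sig[sig$perturbed_gene == g, , drop = FALSE]
      total <- sum(weights[rows$response] * rows$beta)
      assign[[g]] <- data.frame(
        gene = g, role = "regulator",
        programs = paste(sort(rows$response), collapse = "+"),
        predicted_sign = if (abs(total) < tol) NA_real_ else sign(total),
        total_effect = total, stringsAsFactors = FALSE)
    }
  }
  chosen <- content[content$chosen, , drop = FALSE]
  for (i in seq_len(nrow(chosen))) {       # most significant program first
    p <- chosen$program[i]
    for (g in top_loading_genes(loadings, p, n_top)) {
      if (!is.null(assign[[g]]) && assign[[g]]$role == "program_gene") next
      assign[[g]] <- data.frame(
        gene = g, role = "program_gene", programs = prog_names[p],
        predicted_sign = chosen$content_sign[i], total_effect = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, assign)
  if (is.null(out))
    out <- data.frame(gene = character(), role = character(),
                      programs = character(), predicted_sign = numeric(),
                      total_effect = numeric())
  rownames(out) <- NULL
  out[order(out$gene), , drop = FALSE]
}

# shared STEP 1-3 refit used by LOOCV and the permutation test: fixed
# subset size and content count, Mann-Whitney content ranking by default.
refit_model <- function(gamma, eng, loadings, shet, effects, s_reg, n_keep,
                        n_top, fdr = 0.05,
                        drop_gene = NULL, content_method = "mwu",
                        n_perm = 2000L, seed = 7L) {
  G <- eng$G; c_ <- eng$c; yty <- eng$yty; n <- eng$n
  y <- gamma[eng$genes]
  if (!is.null(drop_gene)) {
    i <- match(drop_gene, eng$genes)
    xi <- eng$X[i, ]
    G <- G - tcrossprod(xi)
    c_ <- c_ - xi * y[i]
    yty <- yty - y[i]^2
    n <- n - 1L
  } else if (!identical(unname(y), unname(eng$y))) {
    c_ <- crossprod(eng$X, y)              # permuted gamma, same design
    yty <- sum(y * y)
  }
  K <- eng$K; shet_col <- K + 2L
  best_fit <- NULL; best_sub <- integer()
  if (s_reg > 0L) {
    for (sub in utils::combn(K, s_reg, simplify = FALSE)) {
      f <- subset_fit(eng, c(1L, 1L + sub, shet_col), G, c_, yty, n)
      if (is.null(f)) next
      if (is.null(best_fit) || f$r2 > best_fit$r2) {
        best_fit <- f; best_sub <- sub
      }
    }
  }
  weights <- if (length(best_sub))
    stats::setNames(best_fit$coef[seq_along(best_sub) + 1L],
                    colnames(loadings)[best_sub])
  else stats::setNames(numeric(0), character(0))

  g_used <- if (is.null(drop_gene)) gamma else gamma[names(gamma) != drop_gene]
  L_used <- loadings[rownames(loadings) %in% names(g_used), , drop = FALSE]
  content <- select_content_programs(
    g_used, L_used, shet[names(g_used)], n_top = min(n_top, nrow(L_used)),
    n_perm = n_perm, n_programs_keep = n_keep, seed = seed,
    method = content_method)
  list(weights = weights, subset = best_sub, content = content,
       loadings_used = L_used)
}

# Fisher table of correct predictions: rows = stratum, cols = correct
# yes/no. The reported odds ratio is the sample OR with a Haldane 0.5
# correction when any cell is empty (finite under perfect separation);
# the p-value is the exact test's.
concordance_fisher <- function(correct, stratum) {
  tab <- table(factor(stratum, c("high", "low")),
               factor(correct, c(TRUE, FALSE)))
  ft <- stats::fisher.test(tab)
  t2 <- tab + if (any(tab == 0)) 0.5 else 0
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  list(odds_ratio = unname(or), p = ft$p.value, table = tab)
}

#' STEP 4a: leave-one-out cross-validated sign prediction
#'
#' For each gene in the high-effect (`|gamma| > high_threshold`) or
#' minimal-effect (`|gamma| < low_threshold`) stratum, the model is refit
#' without that gene (subset size and content count fixed at the full-data
#' values; Mann-Whitney content ranking) and the gene's sign is predicted.
#' Fisher's exact test then asks whether correct predictions are enriched
#' among high-effect genes relative to minimal-effect genes.
#'
#' @param gamma,effects_by_program,shet as in [select_regulator_programs()].
#' @param effects `PerturbEffectTable` on programs (per-response FDR).
#' @param loadings gene x K loadings.
#' @param s_reg,n_keep subset size and content count from the full fit.
#' @param n_top content-gene count (default 200).
#' @param high_threshold,low_threshold stratum cutoffs on `|gamma|`.
#' @param fdr regulator significance threshold.
#' @param content_method content ranking inside folds (default fast path).
#' @return list: `odds_ratio`, `fisher_p`, `table`, `predictions`
#'   (data.frame `gene`, `stratum`, `predicted_sign`, `true_sign`,
#'   `correct`).
#' @export
loocv_evaluate <- function(gamma, effects_by_program, shet, effects,
                           loadings, s_reg, n_keep, n_top = 200L,
                           high_threshold = 0.1, low_threshold = 0.01,
                           fdr = 0.05, content_method = "mwu") {
  eng <- subset_engine(gamma, effects_by_program, shet)
  gamma <- gamma[eng$genes]; shet <- shet[eng$genes]
  if (high_threshold > max(abs(gamma)))
    stopf("no gene exceeds high_threshold = %g", high_threshold)
  stratum <- ifelse(abs(gamma) > high_threshold, "high",
                    ifelse(abs(gamma) < low_threshold, "low", NA))
  eval_genes <- eng$genes[!is.na(stratum)]
  if (!any(stratum == "high", na.rm = TRUE) ||
      !any(stratum == "low", na.rm = TRUE))
    stopf("empty stratum at thresholds (%g, %g)", high_threshold,
          low_threshold)
  preds <- lapply(eval_genes, function(g) {
    fit <- refit_model(gamma, eng, loadings, shet, effects, s_reg, n_keep,
                       n_top, fdr, drop_gene = g,
                       content_method = content_method)
    asg <- assign_gene_signs(fit$weights, effects, fit$loadings_used,
                             fit$content, n_top = min(n_top,
                                                      nrow(fit$loadings_used)),
                             fdr = fdr)
    # the left-out gene's own roles, against the fold's model; content
    # membership (defined on loadings, which involve no gamma) takes
    # precedence over the regulator sign, as in the full assignment
    ps <- NA_real_
    chosen <- fit$content[fit$content$chosen, , drop = FALSE]
    for (i in seq_len(nrow(chosen))) {
      top <- top_loading_genes(loadings, chosen$program[i],
                               min(n_top, nrow(loadings)))
      if (g %in% top) { ps <- chosen$content_sign[i]; break }
    }
    if (is.na(ps)) {
      row <- asg[asg$gene == g, , drop = FALSE]
      if (nrow(row)) ps <- row$predicted_sign[1]
    }
    data.frame(gene = g, stratum = stratum[match(g, eng$genes)],
               predicted_sign = ps, true_sign = sign(gamma[g]),
               correct = !is.na(ps) & ps == sign(gamma[g]),
               stringsAsFactors = FALSE)
  })
  preds <- do.call(rbind, preds)
  ft <- concordance_fisher(preds$correct, preds$stratum)
  list(odds_ratio = ft$odds_ratio, fisher_p = ft$p, table = ft$table,
       predictions = preds)
}

#' STEP 4b: gene-label permutation test of the whole model
#'
#' Permutes the gamma labels `n_perm` times; each permutation reruns
#' program selection with the observed subset size and content count
#' (Mann-Whitney fast-path content ranking), reassigns signs, and computes
#' the Fisher p of sign concordance among high-effect genes. The
#' permutation p-value is `(1 + #{perm p <= observed p}) / (n_perm + 1)`.
#'
#' @inheritParams loocv_evaluate
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @param observed_content_method content ranking for the observed fit
#'   (`"permutation"` by default; the fast path is available).
#' @param n_perm_content matched sets for the observed shet-matched ranking.
#' @return list: `permutation_p`, `observed_fisher_p`, `observed_or`,
#'   `perm_fisher_p` (vector).
#' @export
permutation_test <- function(gamma, effects_by_program, shet, effects,
                             loadings, s_reg, n_keep, n_top = 200L,
                             high_threshold = 0.1, fdr = 0.05,
                             n_perm = 20000L, seed = 7L,
                             observed_content_method = "permutation",
                             n_perm_content = 2000L) {
  if (n_perm < 1L) stopf("n_perm must be >= 1")
  eng <- subset_engine(gamma, effects_by_program, shet)
  gamma <- gamma[eng$genes]; shet <- shet[eng$genes]
  stratum <- ifelse(abs(gamma) > high_threshold, "high", "low")

  model_fisher_p <- function(g_vec, content_method, perm_seed) {
    fit <- refit_model(g_vec, eng, loadings, shet, effects, s_reg, n_keep,
                       n_top, fdr, content_method = content_method,
                       n_perm = n_perm_content, seed = perm_seed)
    asg <- assign_gene_signs(fit$weights, effects, loadings, fit$content,
                             n_top = n_top, fdr = fdr)
    ps <- stats::setNames(asg$predicted_sign, asg$gene)[eng$genes]
    correct <- !is.na(ps) & ps == sign(g_vec[eng$genes])
    st <- ifelse(abs(g_vec[eng$genes]) > high_threshold, "high", "low")
    concordance_fisher(correct, st)$p
  }
  obs_p <- model_fisher_p(gamma, observed_content_method, seed)
  perm_p <- with_seed(seed + 1L, {
    vapply(seq_len(n_perm), function(i) {
      gp <- stats::setNames(sample(gamma), names(gamma))
      model_fisher_p(gp, "mwu", seed)
    }, 0)
  })
  list(permutation_p = (1 + sum(perm_p <= obs_p)) / (n_perm + 1),
       observed_fisher_p = obs_p, perm_fisher_p = perm_p)
}

#' Cross-validated variance explained by program sets
#'
#' Repeated 80/20 gene splits: `gamma ~ beta(set) + shet` is fit on the
#' training genes and the out-of-sample R^2 measured on the test genes;
#' reported per candidate set as the mean over splits. The empty set is the
#' shet-only baseline.
#'
#' @inheritParams select_regulator_programs
#' @param chosen_sets named list of integer program-index vectors.
#' @param split training fraction in (0, 1).
#' @param n_splits number of random splits.
#' @param seed integer seed.
#' @return data.frame: `set`, `size`, `mean_test_r2`.
#' @export
crossval_variance_explained <- function(gamma, effects_by_program, shet,
                                        chosen_sets, split = 0.8,
                                        n_splits = 50L, seed = 7L) {
  eng <- subset_engine(gamma, effects_by_program, shet)
  n <- eng$n
  n_train <- floor(split * n)
  if (n_train < 2L || n_train >= n)
    stopf("split = %g leaves an empty train or test set", split)
  splits <- with_seed(seed, lapply(seq_len(n_splits), function(i)
    sample.int(n, n_train)))
  rows <- lapply(seq_along(chosen_sets), function(si) {
    cols <- c(1L, 1L + chosen_sets[[si]], eng$K + 2L)
    r2 <- vapply(splits, function(tr) {
      Xtr <- eng$X[tr, cols, drop = FALSE]; ytr <- eng$y[tr]
      Xte <- eng$X[-tr, cols, drop = FALSE]; yte <- eng$y[-tr]
      b <- try(solve(crossprod(Xtr), crossprod(Xtr, ytr)), silent = TRUE)
      if (inherits(b, "try-error")) return(NA_real_)
      pred <- drop(Xte %*% b)
      1 - sum((yte - pred)^2) / sum((yte - mean(ytr))^2)
    }, 0)
    data.frame(set = names(chosen_sets)[si] %||% paste0("set", si),
               size = length(chosen_sets[[si]]),
               mean_test_r2 = mean(r2, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' STEP 5: assemble and serialize the trait graph
#'
#' Keeps only high-effect genes (`|gamma| > high_threshold`) whose
#' predicted sign matches `sign(gamma)`; multi-path regulators keep every
#' program edge. The graph serializes losslessly to JSON and flattens to an
#' edge TSV (`source`, `target`, `kind`, `sign`, `weight`).
#'
#' @param trait trait identifier.
#' @param gamma named per-gene effect sizes.
#' @param assignments data.frame from [assign_gene_signs()].
#' @param weights named w_p vector for the regulator programs.
#' @param content data.frame from [select_content_programs()].
#' @param effects `PerturbEffectTable` on programs (for edge signs).
#' @param validation optional list (e.g. LOOCV and permutation results).
#' @param high_threshold inclusion cutoff on `|gamma|`.
#' @param fdr regulator edge significance threshold.
#' @return an object of class `trait_graph`.
#' @export
build_graph <- function(trait, gamma, assignments, weights, content,
                        effects, validation = NULL, high_threshold = 0.1,
                        fdr = 0.05) {
  keep <- assignments[!is.na(assignments$predicted_sign) &
                        abs(gamma[assignments$gene]) > high_threshold &
                        assignments$predicted_sign ==
                        sign(gamma[assignments$gene]), , drop = FALSE]
  edges <- list()
  chosen_content <- content[content$chosen, , drop = FALSE]
  for (i in seq_len(nrow(keep))) {
    g <- keep$gene[i]
    if (keep$role[i] == "regulator") {
      for (p in strsplit(keep$programs[i], "+", fixed = TRUE)[[1]]) {
        b <- effects$beta[effects$perturbed_gene == g &
                            effects$response == p][1]
        edges[[length(edges) + 1L]] <- data.frame(
          source = g, target = p, kind = "regulates",
          sign = sign(b), weight = b, stringsAsFactors = FALSE)
      }
    } else {
      edges[[length(edges) + 1L]] <- data.frame(
        source = g, target = keep$programs[i], kind = "member_of",
        sign = keep$predicted_sign[i], weight = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  for (p in names(weights))
    edges[[length(edges) + 1L]] <- data.frame(
      source = p, target = trait, kind = "affects",
      sign = sign(weights[[p]]), weight = weights[[p]],
      stringsAsFactors = FALSE)
  edges <- do.call(rbind, edges)
  structure(list(
    trait = trait,
    regulator_programs = data.frame(program = names(weights),
                                    weight = unname(weights)),
    content_programs = data.frame(program = chosen_content$program,
                                  content_sign = chosen_content$content_sign),
    gene_assignments = keep, edges = edges, validation = validation,
    high_threshold = high_threshold), class = "trait_graph")
}

#' @param graph a `trait_graph`.
#' @param path file path.
#' @rdname build_graph
#' @export
write_trait_graph_json <- function(graph, path) {
  jsonlite::write_json(unclass(graph), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname build_graph
#' @export
read_trait_graph_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("regulator_programs", "content_programs", "gene_assignments",
               "edges"))
    x[[nm]] <- as.data.frame(x[[nm]], stringsAsFactors = FALSE)
  structure(x, class = "trait_graph")
}

#' @rdname build_graph
#' @export
write_graph_edges_tsv <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
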