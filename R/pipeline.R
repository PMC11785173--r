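#' Match factorized programs to reference gene sets
#'
#' Greedy cosine matching: each reference set (e.g. planted program members)
#' is matched to the loading column with the highest cosine similarity
#' between the column and the set's indicator vector.
#'
#' @param loadings gene x K loadings matrix with rownames.
#' @param reference_sets named list of gene-id vectors.
#' @param unique_columns if `TRUE`, assign greedily (best pairs first) so
#'   no two references share a column.
#' @return data.frame with `reference`, `column`, `cosine`.
#' @export
match_programs <- function(loadings, reference_sets,
                           unique_columns = FALSE) {
  S <- vapply(reference_sets, function(set) {
    v <- as.numeric(rownames(loadings) %in% set)
    apply(loadings, 2, function(u)
      sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
  }, numeric(ncol(loadings)))              # columns x references
  if (!unique_columns) {
    rows <- lapply(seq_along(reference_sets), function(j)
      data.frame(reference = names(reference_sets)[j],
                 column = which.max(S[, j]), cosine = max(S[, j]),
                 stringsAsFactors = FALSE))
    return(do.call(rbind, c(rows, list(make.row.names = FALSE))))
  }
  if (length(reference_sets) > ncol(loadings))
    stopf("more reference sets than loading columns for unique matching")
  out <- data.frame(reference = names(reference_sets), column = NA_integer_,
                    cosine = NA_real_, stringsAsFactors = FALSE)
  Sw <- S
  for (step in seq_along(reference_sets)) {
    idx <- arrayInd(which.max(Sw), dim(Sw))
    out$column[idx[2]] <- idx[1]
    out$cosine[idx[2]] <- S[idx[1], idx[2]]
    Sw[idx[1], ] <- -Inf
    Sw[, idx[2]] <- -Inf
  }
  out
}

#' Run the full gene-to-program-to-trait analysis
#'
#' The complete pipeline on observed inputs: cell/gene filtering, consensus
#' NMF of depth-normalised counts, covariate-adjusted perturbation effects
#' on program usages, empirical-Bayes shrinkage of the burden effects, the
#' five graph-building steps, and LOOCV plus label-permutation validation.
#'
#' @param burden data.frame with `gene`, `gamma_hat`, `se`, `shet`.
#' @param cells a `cell_data` object whose perturbation labels are gene ids
#'   from `burden` (plus `"non-targeting"`).
#' @param k number of NMF components (programs plus however many
#'   background components the data need).
#' @param n_runs NMF replicate runs.
#' @param seed seed governing the NMF, permutation and CV randomness.
#' @param min_genes_per_cell,min_cells_per_gene filtering thresholds.
#' @param n_top_content content-gene count per program.
#' @param max_subset largest regulator-program subset searched.
#' @param n_content_keep content programs kept (`NULL` = Bonferroni count).
#' @param fdr regulator significance threshold.
#' @param high_threshold,low_threshold strata cutoffs on `|gamma|`.
#' @param n_perm_content matched sets for the content permutation test.
#' @param n_perm_labels label permutations for the model permutation test.
#' @param prior_bins optional per-gene bin labels for the prior fit.
#' @param trait trait identifier written into the graph.
#' @param run_validation run LOOCV and the permutation test (the slow part).
#' @param components optional component column names (or indices, or a
#'   function of the loadings returning either) to carry into the graph
#'   stage — the analogue of dropping technical or baseline components
#'   after annotating the factorization. `NULL` uses all.
#' @return list with `prior`, `posterior` (burden table with posterior
#'   columns), `decomposition`, `effects`, `effects_by_program` (gene x
#'   component beta matrix), `loadings` (restricted to the burden gene
#'   universe), `selection`, `content`, `assignments`, `loocv`,
#'   `permutation`, `graph`.
#' @export
analyze_trait_graph <- function(burden, cells, k, n_runs = 10L, seed = 7L,
                                min_genes_per_cell = 100L,
                                min_cells_per_gene = 100L,
                                n_top_content = 30L, max_subset = 5L,
                                n_content_keep = NULL, fdr = 0.05,
                                high_threshold = 0.1, low_threshold = 0.01,
                                n_perm_content = 2000L,
                                n_perm_labels = 1000L, prior_bins = NULL,
                                trait = "trait", run_validation = TRUE,
                                components = NULL) {
  cd <- filter_cells_genes(cells, min_genes_per_cell, min_cells_per_gene)
  norm <- sweep(as.matrix(cd$counts), 2,
                1e4 / Matrix::colSums(cd$counts), `*`)
  dec <- run_consensus_nmf(t(norm), k = k, n_runs = n_runs, seed = seed)

  eff <- estimate_effects(cd, dec$usages, fdr_family = "per_response")
  comp <- colnames(dec$loadings)
  genes <- intersect(burden$gene, rownames(dec$loadings))
  B <- matrix(NA_real_, length(genes), length(comp),
              dimnames = list(genes, comp))
  for (p in comp) {
    sub <- eff[eff$response == p, ]
    B[intersect(genes, sub$perturbed_gene), p] <-
      sub$beta[match(intersect(genes, sub$perturbed_gene),
                     sub$perturbed_gene)]
  }
  B <- B[rowSums(is.na(B)) == 0, , drop = FALSE]

  prior <- fit_prior(burden, bins = prior_bins, n_starts = 2L)
  post <- add_posterior(burden, if (is.null(prior_bins)) prior$all else prior,
                        bins = prior_bins)
  gamma <- stats::setNames(post$posterior_mean, post$gene)
  shet <- stats::setNames(post$shet, post$gene)
  L <- dec$loadings[genes, , drop = FALSE]
  if (!is.null(components)) {
    if (is.function(components)) components <- components(L)
    if (is.numeric(components)) components <- colnames(L)[components]
    L <- L[, components, drop = FALSE]
    B <- B[, components, drop = FALSE]
  }

  sel <- select_regulator_programs(gamma, B, shet, max_subset = max_subset,
                                   cv_seed = seed)
  content <- select_content_programs(gamma, L, shet, n_top = n_top_content,
                                     n_perm = n_perm_content,
                                     n_programs_keep = n_content_keep,
                                     seed = seed)
  asg <- assign_gene_signs(sel$weights, eff, L, content,
                           n_top = n_top_content, fdr = fdr)
  loocv <- NULL; perm <- NULL
  if (run_validation) {
    loocv <- loocv_evaluate(gamma, B, shet, eff, L,
                            s_reg = sel$chosen_size,
                            n_keep = sum(content$chosen),
                            n_top = n_top_content,
                            high_threshold = high_threshold,
                            low_threshold = low_threshold, fdr = fdr)
    perm <- permutation_test(gamma, B, shet, eff, L,
                             s_reg = sel$chosen_size,
                             n_keep = sum(content$chosen),
                             n_top = n_top_content,
                             high_threshold = high_threshold, fdr = fdr,
                             n_perm = n_perm_labels, seed = seed,
                             n_perm_content = n_perm_content)
  }
  graph <- build_graph(trait, gamma, asg, sel$weights, content, eff,
                       validation = list(
                         loocv_odds_ratio = loocv$odds_ratio %||% NA_real_,
                         loocv_p = loocv$fisher_p %||% NA_real_,
                         permutation_p = perm$permutation_p %||% NA_real_),
                       high_threshold = high_threshold, fdr = fdr)
  list(prior = prior, posterior = post, decomposition = dec, effects = eff,
       effects_by_program = B, loadings = L, selection = sel,
       content = content, assignments = asg, loocv = loocv,
       permutation = perm, graph = graph)
}
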