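#' Constraint deciles with ties to the lower bin
#'
#' @param shet numeric vector of selection coefficients.
#' @param n_bins number of bins (default 10).
#' @return integer bin per gene in `1..n_bins`.
#' @keywords internal
shet_bins <- function(shet, n_bins = 10L) {
  r <- rank(shet, ties.method = "min")
  b <- ceiling(n_bins * r / length(shet))
  pmax(pmin(b, n_bins), 1L)
}

#' Program burden effect with a constraint-matched permutation null
#'
#' The program burden effect is the mean gamma of the program's `n_top`
#' top-loading genes. Because constraint and `|gamma|` are correlated, the
#' null distribution is built from `n_perm` random gene sets drawn to match
#' the observed set's composition across 10 shet-decile bins exactly. The
#' two-sided permutation p-value
#' `2 * min(#{null >= obs} + 1, #{null <= obs} + 1) / (n_perm + 1)` (capped
#' at 1) carries the sign of the observed mean.
#'
#' @param gamma named per-gene effect sizes (posterior means by default
#'   upstream; raw estimates work identically).
#' @param loadings gene x K loadings matrix (rownames = genes).
#' @param shet named per-gene constraint scores.
#' @param program program index.
#' @param n_top number of top-loading genes defining the program content.
#' @param n_perm number of matched random sets.
#' @param seed integer seed.
#' @return named numeric: `mean_gamma`, `signed_p` (p-value with the sign
#'   of `mean_gamma` attached), `p` (unsigned).
#' @export
program_burden_effect <- function(gamma, loadings, shet, program,
                                  n_top = 100L, n_perm = 10000L, seed = 7L) {
  genes <- sort(rownames(loadings))   # canonical order: invariant to any
  loadings <- loadings[genes, , drop = FALSE]   # joint gene permutation
  if (n_top > length(genes)) stopf("n_top exceeds the gene universe")
  gamma <- gamma[genes]; shet <- shet[genes]
  top <- top_loading_genes(loadings, program, n_top)
  obs <- mean(gamma[top])

  bins <- shet_bins(shet)
  need <- tabulate(bins[match(top, genes)], 10L)
  avail <- tabulate(bins, 10L)
  short <- which(need > avail)
  if (length(short))
    stopf("shet bin %d has %d genes but %d are required for matching",
          short[1], avail[short[1]], need[short[1]])

  null_sums <- with_seed(seed, {
    tot <- numeric(n_perm)
    for (b in which(need > 0L)) {
      g_b <- gamma[bins == b]
      nb <- length(g_b); cb <- need[b]
      tot <- tot + vapply(seq_len(n_perm),
                          function(i) sum(g_b[sample.int(nb, cb)]), 0)
    }
    tot
  })
  null_means <- null_sums / n_top
  eps <- 1e-9 * max(1, abs(obs))      # floating-point-safe tie handling
  p <- min(1, 2 * min(sum(null_means >= obs - eps) + 1,
                      sum(null_means <= obs + eps) + 1) / (n_perm + 1))
  c(mean_gamma = obs, signed_p = sign(obs) * p, p = p)
}

#' Regulator-burden correlation for one response
#'
#' OLS of gamma on the per-gene regulatory effects and shet with intercept:
#' `gamma_x ~ beta_{x->target} + shet_x`. The focal response gene itself is
#' excluded from the regressor vector before fitting.
#'
#' @param gamma named per-gene effect sizes.
#' @param effects named per-gene regulatory effects on the target (gene or
#'   program usage).
#' @param shet named per-gene constraint scores.
#' @param exclude optional gene id dropped before fitting (the target gene).
#' @return named numeric: `coef`, `se`, `p`, `signed_logp`
#'   (`-log10(p) * sign(coef)`), `n`.
#' @export
regulator_burden_correlation <- function(gamma, effects, shet,
                                         exclude = NULL) {
  genes <- Reduce(intersect, list(names(gamma), names(effects), names(shet)))
  if (!is.null(exclude)) {
    if (!exclude %in% genes)
      warnf("exclusion gene '%s' absent from the table", exclude)
    genes <- setdiff(genes, exclude)
  }
  g <- gamma[genes]; b <- effects[genes]; s <- shet[genes]
  ok <- is.finite(g) & is.finite(b) & is.finite(s)
  if (sum(ok) < 10L) stopf("fewer than 10 genes with finite values")
  g <- g[ok]; b <- b[ok]; s <- s[ok]
  if (stats::var(b) == 0) stopf("effects vector is constant (collinear)")
  fit <- stats::lm(g ~ b + s)
  sm <- summary(fit)$coefficients
  coef <- sm["b", 1]; se <- sm["b", 2]; p <- sm["b", 4]
  c(coef = coef, se = se, p = p,
    signed_logp = -log10(max(p, .Machine$double.xmin)) * sign(coef),
    n = length(g))
}

#' Two-sided QQ coordinates for signed log p-values
#'
#' Positive-signed and negative-signed statistics are ranked separately;
#' within each tail the expected values are the uniform order statistics of
#' that tail's test count, so null data lie along the diagonal in both
#' tails regardless of how the signs split.
#'
#' @param signed_logp numeric vector of `-log10(p) * sign` statistics.
#' @return data.frame with `tail` (`"positive"`/`"negative"`), `expected`,
#'   `observed` (-log10 scale); row counts sum to the input length.
#' @export
two_sided_qq <- function(signed_logp) {
  if (length(signed_logp) < 2L) stopf("need at least 2 tests")
  one_tail <- function(vals, label) {
    if (length(vals) == 0L)
      return(data.frame(tail = character(), expected = numeric(),
                        observed = numeric()))
    obs <- sort(abs(vals), decreasing = TRUE)
    data.frame(tail = label,
               expected = -log10(seq_along(obs) / (length(obs) + 1)),
               observed = obs, stringsAsFactors = FALSE)
  }
  rbind(one_tail(signed_logp[signed_logp >= 0], "positive"),
        one_tail(signed_logp[signed_logp < 0], "negative"))
}

#' Fisher enrichment of a hit set among top-ranked genes
#'
#' Builds the 2x2 table (in top-n vs not) x (hit vs not) over the background
#' universe and applies a two-sided Fisher's exact test. The reported odds
#' ratio is the sample OR with a Haldane 0.5 correction when any cell is
#' zero, with a Woolf 95% confidence interval.
#'
#' @param hits character vector of hit genes (subset of `background`).
#' @param ranking named per-gene ranking statistic (smaller = better, e.g. a
#'   p-value); the top `top_n` by this ranking form the "in-top" margin.
#' @param top_n number of top genes.
#' @param background character vector: the gene universe.
#' @return list with `odds_ratio`, `ci95` (length 2), `p`, `table`.
#' @export
top_hit_enrichment <- function(hits, ranking, top_n, background) {
  if (length(hits) == 0L) stopf("empty hit set")
  if (!all(hits %in% background)) stopf("hits must be a subset of background")
  if (top_n > length(background)) stopf("top_n exceeds the background size")
  ranking <- ranking[intersect(names(ranking), background)]
  top <- names(ranking)[order(ranking, names(ranking))][seq_len(top_n)]
  in_top <- background %in% top
  is_hit <- background %in% hits
  tab <- table(factor(in_top, c(TRUE, FALSE)), factor(is_hit, c(TRUE, FALSE)))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  t2 <- tab + if (any(tab == 0)) 0.5 else 0
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  lse <- sqrt(sum(1 / t2))
  ci <- exp(log(or) + c(-1, 1) * 1.96 * lse)
  list(odds_ratio = unname(or), ci95 = unname(ci), p = ft$p.value,
       table = tab)
}

#' Program-trait association scan
#'
#' Computes, for every program, the program burden effect (constraint-
#' matched permutation) and the regulator-burden correlation (regression of
#' gamma on the program's perturbation effects, adjusting for shet).
#'
#' @inheritParams program_burden_effect
#' @param effects_by_program gene x K matrix of perturbation effects on
#'   program usages (beta_{x->P}), rownames = perturbed genes.
#' @return data.frame with one row per program: `program`,
#'   `program_burden_effect`, `pbe_signed_p`, `pbe_p`, `rbc_coef`, `rbc_se`,
#'   `rbc_p`, `rbc_signed_logp`.
#' @export
associate_programs <- function(gamma, loadings, effects_by_program, shet,
                               n_top = 100L, n_perm = 10000L, seed = 7L) {
  K <- ncol(loadings)
  rows <- lapply(seq_len(K), function(p) {
    pbe <- program_burden_effect(gamma, loadings, shet, p, n_top, n_perm,
                                 seed + p)
    rbc <- regulator_burden_correlation(
      gamma, stats::setNames(effects_by_program[, p],
                             rownames(effects_by_program)), shet)
    data.frame(program = p, program_burden_effect = pbe[["mean_gamma"]],
               pbe_signed_p = pbe[["signed_p"]], pbe_p = pbe[["p"]],
               rbc_coef = rbc[["coef"]], rbc_se = rbc[["se"]],
               rbc_p = rbc[["p"]], rbc_signed_logp = rbc[["signed_logp"]])
  })
  do.call(rbind, rows)
}
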