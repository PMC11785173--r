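# Independent oracles used across tests. They share no code with the
# package's integrators: the posterior oracle works on the prior
# probability scale (u = pgamma(gamma)) with stats::integrate, where the
# Gamma weight becomes du and the integrand is bounded.

robust_integrate <- function(f, lo, hi) {
  qs <- seq(lo, hi, length.out = 31)[-c(1, 31)]
  if (hi - lo < 1e-12 || max(f(qs)) * (hi - lo) < 1e-18) return(0)
  for (rt in c(1e-11, 1e-9, 1e-7)) {
    v <- try(stats::integrate(f, lo, hi, rel.tol = rt,
                              subdivisions = 10000L)$value, silent = TRUE)
    if (!inherits(v, "try-error")) return(v)
  }
  stop(attr(v, "condition"))
}

# adaptive-quadrature posterior mean under the signed-Gamma prior
oracle_posterior_mean <- function(gamma_hat, se, prior) {
  a <- prior$alpha; th <- prior$theta
  lh <- function(g) stats::dnorm(gamma_hat, g, se, log = TRUE)
  M <- max(lh(0), lh(gamma_hat), lh(-gamma_hat))
  bi <- function(sgn, k) {
    win <- sgn * gamma_hat + se * c(-12, -6, -2, -1, -.3, 0, .3, 1, 2, 6, 12)
    brk <- sort(unique(c(0, 1, stats::pgamma(win[win > 0], a, scale = th))))
    sum(vapply(seq_len(length(brk) - 1), function(j)
      robust_integrate(function(q) {
        g <- stats::qgamma(q, a, scale = th)
        v <- g^k * exp(lh(sgn * g) - M)
        v[!is.finite(v)] <- 0
        v
      }, brk[j], brk[j + 1]), 0))
  }
  (prior$p * bi(1, 1) - (1 - prior$p) * bi(-1, 1)) /
    (prior$p * bi(1, 0) + (1 - prior$p) * bi(-1, 0))
}

# brute-force two-pass cell/gene filter on a dense matrix
oracle_filter <- function(counts, min_genes, min_cells) {
  m <- as.matrix(counts)
  keep_cells <- colSums(m > 0) >= min_genes
  m <- m[, keep_cells, drop = FALSE]
  keep_genes <- rowSums(m > 0) >= min_cells
  list(cells = colnames(m), genes = rownames(m)[keep_genes])
}

# naive lm-based best-subset enumeration (oracle for select_regulator_programs)
oracle_best_subsets <- function(gamma, B, shet, max_subset) {
  genes <- Reduce(intersect, list(names(gamma), rownames(B), names(shet)))
  y <- gamma[genes]; Bm <- B[genes, , drop = FALSE]; s <- shet[genes]
  K <- ncol(Bm)
  out <- list(`0` = list(subset = integer(),
                         r2 = summary(stats::lm(y ~ s))$r.squared))
  for (sz in seq_len(max_subset)) {
    best_r2 <- -Inf; best_sub <- NULL
    for (sub in utils::combn(K, sz, simplify = FALSE)) {
      fit <- stats::lm(y ~ Bm[, sub, drop = FALSE] + s)
      r2 <- summary(fit)$r.squared
      if (r2 > best_r2) { best_r2 <- r2; best_sub <- sub }
    }
    out[[as.character(sz)]] <- list(subset = best_sub, r2 = best_r2)
  }
  out
}

# small default config used by cell-level tests (kept light on purpose)
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 60L, n_programs = 2L, n_regulators_per_program = 6L,
         n_member_genes_per_program = 8L, n_cells_per_perturbation = 12L,
         n_nontargeting_cells = 150L, n_batches = 2L, mean_depth = 3000,
         trait_noise_sd = 0.05, seed = 5L),
    list(...))
  do.call(sim_config, args)
}
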