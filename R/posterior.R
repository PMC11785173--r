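#' Signed empirical-Bayes prior for burden effect sizes
#'
#' The gene-level trait effect gamma is modelled with a two-part prior:
#' the sign is Bernoulli(p) (probability p of a positive effect) and the
#' magnitude is Gamma(shape alpha, scale theta), shared between the two sign
#' branches. The measurement model is `gamma_hat ~ Normal(gamma, se^2)` with
#' the burden-test standard error known per gene.
#'
#' @param p probability of a positive effect, in (0, 1).
#' @param alpha Gamma shape, > 0.
#' @param theta Gamma scale, > 0.
#' @param feature_bin optional bin identifier for per-bin priors.
#' @return an object of class `prior_params`.
#' @export
prior_params <- function(p, alpha, theta, feature_bin = NA_character_) {
  if (!is.finite(p) || p <= 0 || p >= 1) stopf("p must lie in (0, 1)")
  if (!is.finite(alpha) || alpha <= 0) stopf("alpha must be > 0")
  if (!is.finite(theta) || theta <= 0) stopf("theta must be > 0")
  structure(list(p = p, alpha = alpha, theta = theta,
                 feature_bin = feature_bin), class = "prior_params")
}

#' Prior density of the signed effect size
#'
#' `p * dgamma(gamma; alpha, theta)` for positive gamma and
#' `(1 - p) * dgamma(-gamma; alpha, theta)` for negative gamma. At gamma = 0
#' the continuity limit is returned (0 for alpha > 1, the exponential-density
#' value for alpha = 1, Inf for alpha < 1).
#'
#' @param gamma numeric vector of effect sizes.
#' @param prior a [prior_params()].
#' @return non-negative densities, same length as `gamma`.
#' @export
prior_density <- function(gamma, prior) {
  d <- stats::dgamma(abs(gamma), shape = prior$alpha, scale = prior$theta)
  ifelse(gamma >= 0, prior$p * d, (1 - prior$p) * d)
}

#' Quadrature specification for posterior integrals
#'
#' Each sign branch of the posterior integral is evaluated by composite
#' Gauss-Legendre quadrature: `n_prior_segments` segments log-spaced between
#' the Gamma magnitude quantiles `q_lo` and `q_hi` (geometric segments
#' resolve the integrable singularity at 0 when alpha < 1), refined by
#' `n_like_segments` segments across the likelihood window
#' `gamma_hat +/- 8 se`, with `gl_nodes` Gauss-Legendre nodes per segment.
#' The two branches never share a segment, so the density kink at 0 is
#' never straddled.
#'
#' @param n_prior_segments log-spaced segments per sign branch.
#' @param n_like_segments segments across the likelihood window.
#' @param q_lo,q_hi prior magnitude quantiles bounding the prior-adapted
#'   part of the grid (the likelihood window may extend beyond them).
#' @param gl_nodes Gauss-Legendre nodes per segment.
#' @export
quadrature_spec <- function(n_prior_segments = 64L, n_like_segments = 48L,
                            q_lo = 1e-10, q_hi = 1 - 1e-10,
                            gl_nodes = 15L) {
  structure(list(n_prior_segments = as.integer(n_prior_segments),
                 n_like_segments = as.integer(n_like_segments),
                 q_lo = q_lo, q_hi = q_hi, gl_nodes = as.integer(gl_nodes)),
            class = "quadrature_spec")
}

# Gauss-Legendre nodes/weights on [-1, 1], cached per node count
gl_rule <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (is.null(cache[[key]]))
      cache[[key]] <<- pracma::gaussLegendre(n, -1, 1)
    cache[[key]]
  }
})

# Integrals of {1, gamma} times the unnormalised posterior over one sign
# branch, in units scaled by exp(-log_scale).
branch_integrals <- function(sgn, gamma_hat, se, prior, quad, log_scale) {
  m_lo <- stats::qgamma(quad$q_lo, shape = prior$alpha, scale = prior$theta)
  m_lo <- max(m_lo, 1e-290)     # quantile itself may underflow for tiny alpha
  m_hi <- stats::qgamma(quad$q_hi, shape = prior$alpha, scale = prior$theta)
  brk <- exp(seq(log(m_lo), log(m_hi), length.out = quad$n_prior_segments + 1L))
  win_lo <- sgn * gamma_hat - 8 * se
  win_hi <- sgn * gamma_hat + 8 * se
  if (win_hi > m_lo) {
    win <- seq(max(win_lo, m_lo), max(win_hi, m_lo),
               length.out = quad$n_like_segments + 1L)
    brk <- sort(unique(c(brk, win[win > 0])))
  }
  rule <- gl_rule(quad$gl_nodes)
  lo <- brk[-length(brk)]; hi <- brk[-1]
  half <- (hi - lo) / 2; mid <- (lo + hi) / 2
  g <- rep(mid, each = quad$gl_nodes) +
    rep(half, each = quad$gl_nodes) * rep(rule$x, length(mid))
  wq <- rep(half, each = quad$gl_nodes) * rep(rule$w, length(mid))
  p_branch <- if (sgn > 0) prior$p else 1 - prior$p
  logw <- log(p_branch) +
    stats::dgamma(g, shape = prior$alpha, scale = prior$theta, log = TRUE) +
    stats::dnorm(gamma_hat, mean = sgn * g, sd = se, log = TRUE)
  w <- exp(logw - log_scale)
  w[!is.finite(w)] <- 0
  c(mass = sum(wq * w), first = sum(wq * w * sgn * g), max_logw = max(logw))
}

#' Posterior mean and sign probability of a gene's effect size
#'
#' Combines the signed Gamma prior with the Normal likelihood
#' `N(gamma_hat; gamma, se^2)` by deterministic composite Gauss-Legendre
#' quadrature (see [quadrature_spec()]) and returns the posterior mean and
#' the posterior probability that gamma > 0. `se = 0` short-circuits to
#' `(gamma_hat, 1[gamma_hat > 0])`.
#'
#' @param gamma_hat observed burden effect estimate.
#' @param se its standard error (>= 0).
#' @param prior a [prior_params()].
#' @param quad a [quadrature_spec()].
#' @param gene optional gene id used in error messages.
#' @return named numeric: `posterior_mean`, `posterior_sign_prob`.
#' @export
posterior_summary <- function(gamma_hat, se, prior,
                              quad = quadrature_spec(), gene = NULL) {
  if (se < 0) stopf("se must be >= 0")
  if (se == 0)
    return(c(posterior_mean = gamma_hat,
             posterior_sign_prob = as.numeric(gamma_hat > 0)))
  # first pass locates the scale; second evaluates at that scale
  scale0 <- branch_integrals(1, gamma_hat, se, prior, quad, 0)["max_logw"]
  scale1 <- branch_integrals(-1, gamma_hat, se, prior, quad, 0)["max_logw"]
  m <- max(scale0, scale1)
  if (!is.finite(m))
    stopf("posterior normalizer underflow%s",
          if (is.null(gene)) "" else sprintf(" for gene %s", gene))
  pos <- branch_integrals(1, gamma_hat, se, prior, quad, m)
  neg <- branch_integrals(-1, gamma_hat, se, prior, quad, m)
  z <- pos["mass"] + neg["mass"]
  c(posterior_mean = unname((pos["first"] + neg["first"]) / z),
    posterior_sign_prob = unname(pos["mass"] / z))
}

#' Posterior summaries for a whole burden table
#'
#' @param table data.frame with `gene`, `gamma_hat`, `se` (as from
#'   [simulate_burden_stats()] or [read_burden_tsv()]).
#' @param prior a single [prior_params()] or a named list of per-bin priors.
#' @param bins optional character/factor vector (per gene) selecting the
#'   prior bin when `prior` is a list.
#' @param quad a [quadrature_spec()].
#' @return the input with `posterior_mean` and `posterior_sign_prob` added.
#' @export
add_posterior <- function(table, prior, bins = NULL,
                          quad = quadrature_spec()) {
  get_prior <- function(i) {
    if (inherits(prior, "prior_params")) prior
    else prior[[as.character(bins[i])]]
  }
  out <- t(vapply(seq_len(nrow(table)), function(i) {
    posterior_summary(table$gamma_hat[i], table$se[i], get_prior(i),
                      quad, gene = table$gene[i])
  }, c(posterior_mean = 0, posterior_sign_prob = 0)))
  table$posterior_mean <- out[, 1]
  table$posterior_sign_prob <- out[, 2]
  table
}

# Marginal log-likelihood of the burden table under (p, alpha, theta):
#   L_i = p * I_i(+) + (1-p) * I_i(-),
#   I_i(+/-) = int Gamma(m; a, th) N(gamma_hat_i; +/-m, se_i) dm,
# evaluated for all genes at once by composite Gauss-Legendre on the prior
# probability scale (u = pgamma(m)), where the Gamma weight integrates to
# du and the integrand is bounded.
marginal_loglik <- function(par, gamma_hat, se, n_segments = 60L,
                            gl_nodes = 7L) {
  p <- stats::plogis(par[1]); a <- exp(par[2]); th <- exp(par[3])
  rule <- gl_rule(gl_nodes)
  brk <- seq(0, 1, length.out = n_segments + 1L)
  half <- diff(brk) / 2; mid <- (brk[-1] + brk[-length(brk)]) / 2
  u <- rep(mid, each = gl_nodes) + rep(half, each = gl_nodes) *
    rep(rule$x, n_segments)
  wq <- rep(half, each = gl_nodes) * rep(rule$w, n_segments)
  m <- stats::qgamma(u, shape = a, scale = th)
  pos <- outer(gamma_hat, m, `-`)
  neg <- outer(gamma_hat, m, `+`)
  ipos <- (exp(-(pos / se)^2 / 2) %*% wq) / (se * sqrt(2 * pi))
  ineg <- (exp(-(neg / se)^2 / 2) %*% wq) / (se * sqrt(2 * pi))
  lik <- p * ipos + (1 - p) * ineg
  sum(log(pmax(lik, 1e-300)))
}

#' Fit the signed-Gamma prior by marginal maximum likelihood
#'
#' Maximises `sum_i log int f(gamma) N(gamma_hat_i; gamma, se_i^2) dgamma`
#' over `(p, alpha, theta)` by bounded quasi-Newton optimisation on
#' transformed parameters, with multiple starts. With `bins`, a separate
#' prior is fitted per bin (e.g. shet deciles), the spirit of
#' feature-conditional empirical-Bayes priors without a learned regressor.
#'
#' @param table data.frame with `gamma_hat` and `se` columns.
#' @param bins optional per-gene bin labels; each bin needs >= 50 genes.
#' @param n_starts number of optimisation starts.
#' @return a named list of `prior_params` (one per bin; single unnamed-bin
#'   fit returned under `"all"`), each carrying attributes `loglik`,
#'   `convergence`, and `p_unidentifiable`.
#' @export
fit_prior <- function(table, bins = NULL, n_starts = 3L) {
  if (is.null(bins)) bins <- rep("all", nrow(table))
  bins <- as.character(bins)
  fits <- lapply(split(seq_len(nrow(table)), bins), function(idx) {
    gh <- table$gamma_hat[idx]; se <- table$se[idx]
    if (length(idx) < 50L)
      stopf("prior fitting needs >= 50 genes per bin (got %d)", length(idx))
    if (any(se <= 0)) stopf("se must be > 0 for every gene used in fitting")
    # moment-flavoured starts around the excess spread of gamma_hat over se
    spread <- sqrt(max(mean(gh^2) - mean(se^2), 1e-6))
    starts <- list(
      c(stats::qlogis(0.5), log(1.5), log(spread / 1.5)),
      c(stats::qlogis(mean(gh > 0) * 0.98 + 0.01), log(2), log(spread / 2)),
      c(stats::qlogis(0.5), log(0.8), log(spread)))
    starts <- starts[seq_len(min(n_starts, length(starts)))]
    best <- NULL
    for (s in starts) {
      fit <- try(stats::optim(s, function(par)
        -marginal_loglik(par, gh, se), method = "Nelder-Mead",
        control = list(maxit = 500, reltol = 1e-10)), silent = TRUE)
      if (inherits(fit, "try-error")) next
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    if (is.null(best)) stopf("prior optimisation failed in every start")
    par <- best$par
    ll <- -best$value
    # p is unidentifiable when the data carry no sign information
    ll_flat <- marginal_loglik(c(stats::qlogis(0.5), par[2], par[3]),
                               gh, se)
    pr <- prior_params(stats::plogis(par[1]), exp(par[2]), exp(par[3]))
    attr(pr, "loglik") <- ll
    attr(pr, "convergence") <- best$convergence
    attr(pr, "p_unidentifiable") <- (ll - ll_flat) < 1e-3
    pr
  })
  fits
}

#' Sign-replication concordance of top-ranked genes
#'
#' Ranks genes by `|ranking_scores|` (descending, ties broken by gene id)
#' and returns the fraction of the top `top_n` whose discovery-cohort sign
#' matches the sign of the replication-cohort z-score.
#'
#' @param ranking_scores named numeric vector (names = gene ids).
#' @param discovery_signs named vector of discovery signs (+1/-1).
#' @param replication_z named numeric vector of replication z-scores.
#' @param top_n number of top genes to evaluate.
#' @return fraction in `[0, 1]`.
#' @export
sign_replication_concordance <- function(ranking_scores, discovery_signs,
                                         replication_z, top_n) {
  if (top_n <= 0) stopf("top_n must be positive")
  common <- Reduce(intersect, list(names(ranking_scores),
                                   names(discovery_signs),
                                   names(replication_z)))
  if (top_n > length(common))
    stopf("top_n (%d) exceeds the %d genes present in all tables",
          top_n, length(common))
  s <- ranking_scores[common]
  ord <- common[order(-abs(s), common)]
  top <- ord[seq_len(top_n)]
  mean(sign(discovery_signs[top]) == sign(replication_z[top]))
}
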