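#' Significant regulators of a program
#'
#' Genes whose perturbation shifts the program's usage at `fdr <
#' fdr_threshold` (FDR computed within the per-response family, i.e. across
#' regulators of that program). Fewer than 4 significant regulators makes
#' the Fisher-z variance `1/(N-3)` degenerate, so such sets are flagged
#' untestable.
#'
#' @param effects a `PerturbEffectTable` data.frame (from
#'   [estimate_effects()] with `fdr_family = "per_response"`) restricted or
#'   restrictable to one response program.
#' @param response the program/response id to extract regulators for.
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @return list with `genes`, `beta` (named effect sizes on this program),
#'   `untestable` (logical).
#' @export
significant_regulators <- function(effects, response,
                                   fdr_threshold = 0.05) {
  sub <- effects[effects$response == response & !effects$self, , drop = FALSE]
  sig <- sub[sub$fdr < fdr_threshold, , drop = FALSE]
  list(genes = sig$perturbed_gene,
       beta = stats::setNames(sig$beta, sig$perturbed_gene),
       untestable = nrow(sig) < 4L)
}

#' Gaussian approximate likelihood fits of the four directionality models
#'
#' The observed Fisher-z statistics are modelled as
#' `zhat_i ~ N(Z_i, 1/(n_i - 3))`. The four hypotheses are M1 (p1 causes
#' p2: `Z2 = 0`, `Z1` free), M2 (p2 causes p1: `Z1 = 0`, `Z2` free), M3 (no
#' relationship: `Z1 = Z2 = 0`) and M4 (ascertainment-independent shared
#' correlation: `Z1 = Z2 = Z*`, the precision-weighted mean). AIC is
#' `2k - 2 loglik` with k free parameters (1, 1, 0, 1).
#'
#' @param z1_hat,z2_hat observed Fisher-z values for the two ascertainment
#'   directions.
#' @param n1,n2 significant-regulator counts (both must be >= 4).
#' @return data.frame with rows M1..M4: `model`, `loglik`, `k_params`, `aic`.
#' @export
fit_four_models <- function(z1_hat, n1, z2_hat, n2) {
  if (n1 <= 3L || n2 <= 3L) stopf("need n >= 4 in both directions")
  s1 <- sqrt(1 / (n1 - 3)); s2 <- sqrt(1 / (n2 - 3))
  ll <- function(mu1, mu2)
    stats::dnorm(z1_hat, mu1, s1, log = TRUE) +
    stats::dnorm(z2_hat, mu2, s2, log = TRUE)
  zstar <- ((n1 - 3) * z1_hat + (n2 - 3) * z2_hat) / ((n1 - 3) + (n2 - 3))
  fits <- data.frame(
    model = c("M1", "M2", "M3", "M4"),
    loglik = c(ll(z1_hat, 0), ll(0, z2_hat), ll(0, 0), ll(zstar, zstar)),
    k_params = c(1L, 1L, 0L, 1L), stringsAsFactors = FALSE)
  fits$aic <- 2 * fits$k_params - 2 * fits$loglik
  fits
}

#' Relative-likelihood verdict for a program pair
#'
#' `r = exp((AIC_causal - AIC_noncausal) / 2)` where AIC_causal is the
#' smaller of AIC(M1), AIC(M2) and AIC_noncausal the smaller of AIC(M3),
#' AIC(M4). The verdict is causal toward the winning causal model iff
#' `r < threshold` (default 0.01).
#'
#' @param aic named numeric or the data.frame from [fit_four_models()].
#' @param threshold relative-likelihood cutoff.
#' @return list with `r` and `verdict` in
#'   `{"p1_causes_p2", "p2_causes_p1", "non_causal"}`.
#' @export
pair_verdict <- function(aic, threshold = 0.01) {
  if (is.data.frame(aic)) aic <- stats::setNames(aic$aic, aic$model)
  aic_causal <- min(aic[["M1"]], aic[["M2"]])
  aic_noncausal <- min(aic[["M3"]], aic[["M4"]])
  r <- exp((aic_causal - aic_noncausal) / 2)
  verdict <- if (r < threshold) {
    if (aic[["M1"]] <= aic[["M2"]]) "p1_causes_p2" else "p2_causes_p1"
  } else "non_causal"
  list(r = r, verdict = verdict)
}

# Fisher z with |rho| = 1 clamped just inside the open interval
fisher_z <- function(rho) {
  if (any(abs(rho) >= 1)) {
    warnf("|rho| = 1 clamped to 1 - 1e-12 before Fisher z")
    rho <- pmin(pmax(rho, -(1 - 1e-12)), 1 - 1e-12)
  }
  atanh(rho)
}

#' Asymmetric-correlation causal test for one program pair
#'
#' Ascertains the significant regulators of each program, computes the
#' Spearman correlation of their effects on the two programs within each
#' ascertainment set (average ranks for ties), Fisher-z transforms both, and
#' compares the four directionality models by AIC.
#'
#' @param effects `PerturbEffectTable` with per-response FDR covering both
#'   programs.
#' @param p1,p2 response ids of the two programs.
#' @param fdr_threshold regulator significance cutoff.
#' @param threshold relative-likelihood cutoff for a causal verdict.
#' @return a `causal_pair_result` list: `p1`, `p2`, `n1`, `n2`, `rho1`,
#'   `rho2`, `z1`, `z2`, `models` (AIC table), `r`, `verdict`, `untestable`.
#' @export
causal_pair <- function(effects, p1, p2, fdr_threshold = 0.05,
                        threshold = 0.01) {
  get_beta <- function(resp, genes) {
    sub <- effects[effects$response == resp &
                     effects$perturbed_gene %in% genes, , drop = FALSE]
    stats::setNames(sub$beta, sub$perturbed_gene)
  }
  r1 <- significant_regulators(effects, p1, fdr_threshold)
  r2 <- significant_regulators(effects, p2, fdr_threshold)
  base <- list(p1 = p1, p2 = p2, n1 = length(r1$genes), n2 = length(r2$genes))
  if (r1$untestable || r2$untestable)
    return(structure(c(base, list(untestable = TRUE, verdict = "untestable",
                                  r = NA_real_)), class = "causal_pair_result"))
  b1_on_1 <- r1$beta
  b1_on_2 <- get_beta(p2, r1$genes)[names(b1_on_1)]
  b2_on_2 <- r2$beta
  b2_on_1 <- get_beta(p1, r2$genes)[names(b2_on_2)]
  rho1 <- stats::cor(b1_on_1, b1_on_2, method = "spearman")
  rho2 <- stats::cor(b2_on_2, b2_on_1, method = "spearman")
  z1 <- fisher_z(rho1); z2 <- fisher_z(rho2)
  models <- fit_four_models(z1, base$n1, z2, base$n2)
  v <- pair_verdict(models, threshold)
  structure(c(base, list(rho1 = rho1, rho2 = rho2, z1 = z1, z2 = z2,
                         models = models, r = v$r, verdict = v$verdict,
                         untestable = FALSE)),
            class = "causal_pair_result")
}

#' Causal scan over all program pairs
#'
#' @inheritParams causal_pair
#' @param responses program/response ids to scan (default: all in `effects`).
#' @return data.frame with one row per unordered pair: `p1`, `p2`, `n1`,
#'   `n2`, `rho1`, `rho2`, `z1`, `z2`, AICs of M1..M4, `r`, `verdict`.
#' @export
causal_scan <- function(effects, responses = unique(effects$response),
                        fdr_threshold = 0.05, threshold = 0.01) {
  pairs <- utils::combn(responses, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    res <- causal_pair(effects, pr[1], pr[2], fdr_threshold, threshold)
    data.frame(p1 = pr[1], p2 = pr[2], n1 = res$n1, n2 = res$n2,
               rho1 = res$rho1 %||% NA_real_, rho2 = res$rho2 %||% NA_real_,
               z1 = res$z1 %||% NA_real_, z2 = res$z2 %||% NA_real_,
               aic_m1 = if (res$untestable) NA_real_ else res$models$aic[1],
               aic_m2 = if (res$untestable) NA_real_ else res$models$aic[2],
               aic_m3 = if (res$untestable) NA_real_ else res$models$aic[3],
               aic_m4 = if (res$untestable) NA_real_ else res$models$aic[4],
               r = res$r, verdict = res$verdict, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
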