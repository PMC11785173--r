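# Planted gene-program-trait scenario at the effect-table level (no cell
# simulation): fast, exact control over the signal available to the
# graph-building steps. Program 2 is planted "discordant": its regulator
# path and its content contribution pull the trait in opposite directions.
planted_scenario <- function(n_genes = 300L, K = 3L, n_reg = 25L,
                             n_mem = 40L,
                             w = c(0.6, -0.5, 0.4)[seq_len(K)],
                             content = c(0.2, 0.15, 0.1)[seq_len(K)],
                             gamma_noise = 0.02, eff_se = 0.05,
                             seed = 101L) {
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  pn <- paste0("P", seq_len(K))
  reg_idx <- split(seq_len(K * n_reg), rep(seq_len(K), each = n_reg))
  mem_idx <- split(K * n_reg + seq_len(K * n_mem),
                   rep(seq_len(K), each = n_mem))

  B_true <- matrix(0, n_genes, K, dimnames = list(genes, pn))
  for (p in seq_len(K))
    B_true[reg_idx[[p]], p] <- sample(c(-1, 1), n_reg, TRUE) *
      runif(n_reg, 0.5, 1.5)

  L <- matrix(runif(n_genes * K, 0, 0.01), n_genes, K,
              dimnames = list(genes, pn))
  member_ind <- matrix(0, n_genes, K)
  for (p in seq_len(K)) {
    L[mem_idx[[p]], p] <- 1 + abs(rnorm(n_mem, 0, 0.1))
    member_ind[mem_idx[[p]], p] <- 1
  }

  gamma <- drop(B_true %*% w) + drop(member_ind %*% content) +
    rnorm(n_genes, 0, gamma_noise)
  names(gamma) <- genes
  shet <- setNames(rbeta(n_genes, 2, 5), genes)

  B_hat <- B_true + matrix(rnorm(n_genes * K, 0, eff_se), n_genes)
  eff <- do.call(rbind, lapply(seq_len(K), function(p) {
    z <- B_hat[, p] / eff_se
    data.frame(perturbed_gene = genes, response = pn[p],
               beta = unname(B_hat[, p]), se = eff_se,
               p_value = 2 * pnorm(-abs(z)), self = FALSE,
               stringsAsFactors = FALSE)
  }))
  eff$fdr <- stats::ave(eff$p_value, eff$response,
                        FUN = function(p) p.adjust(p, "BH"))
  attr(eff, "fdr_family") <- "per_response"

  list(genes = genes, gamma = gamma, shet = shet, B = B_hat,
       B_true = B_true, loadings = L, effects = eff, w = w,
       content = content,
       regulators = lapply(reg_idx, function(i) genes[i]),
       members = lapply(mem_idx, function(i) genes[i]))
}
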