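#' Decay-weighted ChIP regulation scores per TF and gene
#'
#' `S(i, j) = sum_k P(i, k) * exp(-x(i, j, k) / d)` where `P` is the peak
#' strength (-log10 q), `x` the distance in bp from the peak's reference
#' point to the gene's TSS (same chromosome only; other chromosomes
#' contribute 0), and `d` the decay distance. The reference point is the
#' summit (`start + summit_offset`) when a non-negative offset is present,
#' otherwise the integer-floored peak midpoint. Coordinates are 0-based
#' half-open BED throughout; strand is ignored for distances.
#'
#' @param peaks data.frame with `tf`, `chrom`, `start`, `end`, `strength`
#'   and optional `summit_offset` (as from [read_narrowpeak()]).
#' @param tss data.frame with `chrom`, `start`, `gene` (TSS at `start`).
#' @param decay_bp decay distance in bp (5000 or 50000 in practice).
#' @return TF x gene numeric matrix of scores.
#' @export
compute_chip_scores <- function(peaks, tss, decay_bp = 5000) {
  if (decay_bp <= 0) stopf("decay_bp must be > 0")
  if (any(peaks$start < 0) || any(tss$start < 0))
    stopf("negative coordinates are not a valid BED interval")
  if (any(peaks$start >= peaks$end)) stopf("peak start must be < end")
  center <- floor((peaks$start + peaks$end) / 2)
  if ("summit_offset" %in% names(peaks)) {
    has_summit <- !is.na(peaks$summit_offset) & peaks$summit_offset >= 0
    center[has_summit] <- peaks$start[has_summit] +
      peaks$summit_offset[has_summit]
  }
  tfs <- sort(unique(peaks$tf))
  S <- matrix(0, length(tfs), nrow(tss),
              dimnames = list(tfs, tss$gene))
  for (chr in unique(tss$chrom)) {
    g_idx <- which(tss$chrom == chr)
    p_idx <- which(peaks$chrom == chr)
    if (length(p_idx) == 0L) next
    dist <- abs(outer(center[p_idx], tss$start[g_idx], `-`))
    w <- peaks$strength[p_idx] * exp(-dist / decay_bp)
    contrib <- rowsum(w, peaks$tf[p_idx])
    S[rownames(contrib), g_idx] <- S[rownames(contrib), g_idx, drop = FALSE] +
      contrib
  }
  S
}

#' Classify TFs as activators/inhibitors from knockdown DEGs
#'
#' For each TF and each decay distance, Mann-Whitney U tests compare the
#' TF's ChIP scores over its down-regulated DEGs (activator test) and its
#' up-regulated DEGs (inhibitor test) against the background with all of
#' that TF's DEGs removed. The decay with the stronger DEG correspondence
#' (smaller minimum p across the two tests) is retained per TF, and flags
#' are set where the BH FDR across TFs falls below `fdr`.
#'
#' @param scores_by_decay named list of TF x gene score matrices, one per
#'   decay choice (names e.g. `"5000"`, `"50000"`); a single matrix is
#'   accepted for a single-decay analysis.
#' @param deg_up,deg_down named lists (per TF) of up-/down-regulated DEG
#'   gene sets after knockdown of that TF.
#' @param background character vector: the expressed-gene universe.
#' @param fdr flag threshold (default 0.05).
#' @return data.frame per TF: `tf`, `decay` (chosen), `p_activator`,
#'   `p_inhibitor`, `fdr_activator`, `fdr_inhibitor`, `activator`,
#'   `inhibitor` (logical flags).
#' @export
classify_tf_direction <- function(scores_by_decay, deg_up, deg_down,
                                  background, fdr = 0.05) {
  if (length(background) == 0L) stopf("empty background")
  if (is.matrix(scores_by_decay))
    scores_by_decay <- list(default = scores_by_decay)
  tfs <- rownames(scores_by_decay[[1]])
  one_p <- function(sc, degs, other_degs) {
    degs <- intersect(degs, background)
    bg <- setdiff(background, union(degs, other_degs))
    if (length(degs) == 0L || length(bg) == 0L) return(NA_real_)
    x <- sc[degs]; y <- sc[bg]
    if (stats::sd(c(x, y)) == 0) return(1)
    stats::wilcox.test(x, y, alternative = "greater", exact = FALSE)$p.value
  }
  rows <- lapply(tfs, function(tf) {
    up <- deg_up[[tf]] %||% character()
    down <- deg_down[[tf]] %||% character()
    per_decay <- lapply(names(scores_by_decay), function(d) {
      sc <- scores_by_decay[[d]][tf, ]
      c(p_act = one_p(sc, down, up), p_inh = one_p(sc, up, down))
    })
    pmin_d <- vapply(per_decay, function(v) {
      v <- v[is.finite(v)]
      if (length(v)) min(v) else 1      # TF without usable DEG sets
    }, 0)
    pick <- which.min(pmin_d)
    data.frame(tf = tf, decay = names(scores_by_decay)[pick],
               p_activator = per_decay[[pick]][["p_act"]],
               p_inhibitor = per_decay[[pick]][["p_inh"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_activator <- bh_adjust(out$p_activator)
  out$fdr_inhibitor <- bh_adjust(out$p_inhibitor)
  out$activator <- !is.na(out$fdr_activator) & out$fdr_activator < fdr
  out$inhibitor <- !is.na(out$fdr_inhibitor) & out$fdr_inhibitor < fdr
  out
}

#' TF binding enrichment in program top-loading genes
#'
#' One-sided Mann-Whitney U test (program genes have higher ChIP scores)
#' per classified TF per program, BH-corrected across the TF x program
#' family. When usage effects are supplied, each row also reports the TF's
#' direct perturbation effect on the program's activity, pairing binding
#' enrichment with regulatory evidence.
#'
#' @param scores TF x gene score matrix (at each TF's chosen decay).
#' @param dec a `program_decomposition` (or gene x K loadings matrix).
#' @param n_top program-defining top-loading gene count (default 300).
#' @param classified_tfs character vector of TFs to test (e.g. those flagged
#'   by [classify_tf_direction()]); must be non-empty.
#' @param usage_effects optional `PerturbEffectTable` of effects on program
#'   usages, used to attach `usage_beta` and `usage_fdr` per (TF, program).
#' @return data.frame per (program, TF): `program`, `tf`, `p`, `fdr`, and
#'   optionally `usage_beta`, `usage_fdr`.
#' @export
annotate_program_tfs <- function(scores, dec, n_top = 300L, classified_tfs,
                                 usage_effects = NULL) {
  if (length(classified_tfs) == 0L) stopf("no classified TFs supplied")
  L <- if (inherits(dec, "program_decomposition")) dec$loadings else dec
  genes <- intersect(rownames(L), colnames(scores))
  if (n_top > length(genes)) stopf("n_top exceeds the scored gene universe")
  L <- L[genes, , drop = FALSE]
  rows <- list()
  for (p in seq_len(ncol(L))) {
    top <- top_loading_genes(L, p, n_top)
    rest <- setdiff(genes, top)
    for (tf in classified_tfs) {
      sc <- scores[tf, genes]
      pval <- if (stats::sd(sc) == 0) 1 else
        stats::wilcox.test(sc[top], sc[rest], alternative = "greater",
                           exact = FALSE)$p.value
      rows[[length(rows) + 1L]] <- data.frame(program = p, tf = tf, p = pval,
                                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  if (!is.null(usage_effects)) {
    key <- paste(usage_effects$perturbed_gene, usage_effects$response)
    resp <- colnames(L) %||% paste0("P", seq_len(ncol(L)))
    m <- match(paste(out$tf, resp[out$program]), key)
    out$usage_beta <- usage_effects$beta[m]
    out$usage_fdr <- usage_effects$fdr[m]
  }
  out
}
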