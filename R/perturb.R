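#' Filter cells then genes by expression breadth
#'
#' Removes cells expressing fewer than `min_genes_per_cell` genes, then
#' genes expressed in fewer than `min_cells_per_gene` of the surviving cells
#' (a single pass, in that order). Perturbation labels and covariates are
#' carried along.
#'
#' @param data a `cell_data` object.
#' @param min_genes_per_cell minimum genes expressed per retained cell.
#' @param min_cells_per_gene minimum cells expressing a retained gene.
#' @return the filtered `cell_data`.
#' @export
filter_cells_genes <- function(data, min_genes_per_cell = 500L,
                               min_cells_per_gene = 500L) {
  if (min_genes_per_cell < 0 || min_cells_per_gene < 0)
    stopf("thresholds must be >= 0")
  expressed <- data$counts > 0
  keep_cells <- Matrix::colSums(expressed) >= min_genes_per_cell
  if (!any(keep_cells)) stopf("all cells removed by the cell filter")
  counts <- data$counts[, keep_cells, drop = FALSE]
  keep_genes <- Matrix::rowSums(counts > 0) >= min_cells_per_gene
  counts <- counts[keep_genes, , drop = FALSE]
  structure(list(counts = counts,
                 cells = data$cells[keep_cells, , drop = FALSE],
                 genes = rownames(counts),
                 mito_genes = intersect(data$mito_genes, rownames(counts))),
            class = "cell_data")
}

#' Depth-normalised log expression
#'
#' `ln(1 + count * scale / cell_total)` per entry; invariant to scaling a
#' cell's counts and its total together.
#'
#' @param data a `cell_data` object (or a counts matrix).
#' @param scale target depth (default 1e4).
#' @return a gene x cell matrix of log-normalised values (dense).
#' @export
lognormalize <- function(data, scale = 1e4) {
  counts <- if (inherits(data, "cell_data")) data$counts else data
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) {
    bad <- colnames(counts)[which(totals == 0)][1]
    stopf("cell '%s' has zero total counts; filter cells first", bad)
  }
  m <- as.matrix(counts)
  log1p(sweep(m, 2, scale / totals, `*`))
}

# Build the covariate design shared by all targets: intercept, batch one-hot
# (first level dropped), n_genes_expressed, pct_mito.
covariate_design <- function(cells) {
  batch <- factor(cells$batch)
  X <- cbind(`(Intercept)` = 1,
             n_genes_expressed = cells$n_genes_expressed,
             pct_mito = cells$pct_mito)
  if (nlevels(batch) > 1L) {
    B <- stats::model.matrix(~batch)[, -1, drop = FALSE]
    X <- cbind(X, B)
  }
  X
}

#' Covariate-adjusted perturbation effects on genes or programs
#'
#' For each target perturbation x and each response column r (log-normalised
#' gene expression or program usage), fits by ordinary least squares on the
#' cells `{perturbation = x} + {non-targeting}`:
#' `response ~ intercept + is_perturbed + batch + n_genes_expressed +
#' pct_mito` and reports the `is_perturbed` coefficient with its exact
#' two-sided t-test. FDR is Benjamini-Hochberg within the declared family:
#' `per_perturbation` (across responses within each target; natural for
#' gene-level beta) or `per_response` (across targets within each response;
#' natural for program usages, where it defines each program's significant
#' regulator set).
#'
#' @param data a `cell_data` object (for labels and covariates).
#' @param responses cell x response numeric matrix, rows aligned with
#'   `data$cells` (cells as rows; e.g. `t(lognormalize(data))` or usages).
#' @param targets perturbation labels to test (default: all non-control
#'   labels with enough cells).
#' @param fdr_family `"per_perturbation"` or `"per_response"`.
#' @param min_cells minimum perturbed and control cells per target.
#' @param moderate if `TRUE`, squeeze residual variances toward their mean
#'   (a simple empirical-Bayes moderation of the t-test denominators).
#' @return data.frame with `perturbed_gene`, `response`, `beta`, `se`,
#'   `p_value`, `fdr`, `self` (flag for x = y rows), plus a `skipped`
#'   attribute listing targets without enough cells or with degenerate
#'   designs.
#' @export
estimate_effects <- function(data, responses,
                             targets = NULL,
                             fdr_family = c("per_perturbation", "per_response"),
                             min_cells = 10L, moderate = FALSE) {
  fdr_family <- match.arg(fdr_family)
  cells <- data$cells
  if (nrow(responses) != nrow(cells))
    stopf("responses must have one row per cell (%d vs %d)",
          nrow(responses), nrow(cells))
  if (is.null(colnames(responses)))
    colnames(responses) <- paste0("R", seq_len(ncol(responses)))
  is_nt <- cells$perturbation == "non-targeting"
  if (sum(is_nt) < min_cells) stopf("fewer than %d non-targeting cells", min_cells)
  if (is.null(targets)) {
    tab <- table(cells$perturbation[!is_nt])
    targets <- names(tab)[tab >= min_cells]
  }
  Xc <- covariate_design(cells)
  out <- vector("list", length(targets))
  skipped <- character()
  for (ti in seq_along(targets)) {
    x <- targets[ti]
    sel <- which(is_nt | cells$perturbation == x)
    n_pert <- sum(cells$perturbation[sel] == x)
    if (n_pert < min_cells) { skipped <- c(skipped, x); next }
    X <- cbind(Xc[sel, 1, drop = FALSE],
               is_perturbed = as.numeric(cells$perturbation[sel] == x),
               Xc[sel, -1, drop = FALSE])
    # drop covariate columns constant within this subset
    keep <- c(TRUE, TRUE, apply(X[, -(1:2), drop = FALSE], 2,
                                function(v) stats::var(v) > 0))
    X <- X[, keep, drop = FALSE]
    qr_x <- qr(X)
    if (qr_x$rank < ncol(X)) {
      piv <- qr_x$pivot[seq_len(qr_x$rank)]
      if (!(2L %in% piv)) { skipped <- c(skipped, x); next }
      X <- X[, sort(piv), drop = FALSE]
      qr_x <- qr(X)
    }
    Y <- responses[sel, , drop = FALSE]
    cf <- qr.coef(qr_x, Y)
    res <- qr.resid(qr_x, Y)
    dfree <- nrow(X) - qr_x$rank
    s2 <- colSums(res^2) / dfree
    if (moderate) s2 <- 0.5 * s2 + 0.5 * mean(s2)
    jj <- which(qr_x$pivot == 2L)    # position of is_perturbed after pivoting
    XtXinv_jj <- chol2inv(qr.R(qr_x))[jj, jj]
    beta <- cf["is_perturbed", ]
    se <- sqrt(s2 * XtXinv_jj)
    tstat <- ifelse(se > 0, beta / se, 0)
    p <- 2 * stats::pt(abs(tstat), df = dfree, lower.tail = FALSE)
    # degenerate responses (zero variance) get beta 0, p 1 by convention
    degen <- apply(Y, 2, function(v) stats::var(v) == 0)
    beta[degen] <- 0; se[degen] <- 0; p[degen] <- 1
    out[[ti]] <- data.frame(perturbed_gene = x, response = colnames(responses),
                            beta = unname(beta), se = unname(se),
                            p_value = unname(p),
                            self = colnames(responses) == x,
                            stringsAsFactors = FALSE)
  }
  eff <- do.call(rbind, out)
  if (is.null(eff)) stopf("no target had >= %d perturbed cells", min_cells)
  eff$fdr <- if (fdr_family == "per_perturbation") {
    stats::ave(eff$p_value, eff$perturbed_gene, FUN = bh_adjust)
  } else {
    stats::ave(eff$p_value, eff$response, FUN = bh_adjust)
  }
  attr(eff, "fdr_family") <- fdr_family
  attr(eff, "skipped") <- skipped
  eff
}

#' Assign cells to cell-cycle phases from marker scores
#'
#' Scores each cell as the mean of z-scored (across cells) log-normalised
#' marker expression for the S and G2/M marker sets; the phase is the argmax
#' of the two scores when that maximum is positive, else G1.
#'
#' @param data a `cell_data` object.
#' @param s_markers,g2m_markers character vectors of marker gene ids.
#' @param logmat optional precomputed log-normalised matrix (gene x cell).
#' @return character vector of phases (`"G1"`, `"S"`, `"G2M"`), one per cell.
#' @export
assign_cell_cycle_phase <- function(data, s_markers, g2m_markers,
                                    logmat = lognormalize(data)) {
  score <- function(markers) {
    mk <- intersect(markers, rownames(logmat))
    if (length(mk) == 0L) stopf("no marker genes present in the data")
    sub <- logmat[mk, , drop = FALSE]
    z <- t(scale(t(sub)))
    z[is.nan(z)] <- 0          # constant marker across cells carries no signal
    colMeans(z)
  }
  s <- score(s_markers); g2m <- score(g2m_markers)
  phase <- rep("G1", length(s))
  mx <- pmax(s, g2m)
  phase[mx > 0 & s >= g2m] <- "S"
  phase[mx > 0 & g2m > s] <- "G2M"
  phase
}

#' Phase fractions per perturbation with jackknife standard errors
#'
#' Leave-one-cell-out fractions per group; the jackknife SE is
#' `sqrt((n - 1)/n * sum_i (f_i - mean(f_i))^2)`.
#'
#' @param phases per-cell phase labels.
#' @param groups per-cell perturbation labels.
#' @return data.frame with `group`, `phase`, `fraction`, `se`; groups with
#'   fewer than 2 cells are excluded with a warning.
#' @export
phase_fractions_jackknife <- function(phases, groups) {
  lv <- sort(unique(phases))
  out <- list()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    n <- length(idx)
    if (n < 2L) {
      warnf("group '%s' has fewer than 2 cells; excluded", g)
      next
    }
    ph <- phases[idx]
    for (p in lv) {
      k <- sum(ph == p)
      f <- k / n
      # leave-one-out fractions take only two values: drop a p-cell or not
      f_loo <- c(rep((k - 1) / (n - 1), k), rep(k / (n - 1), n - k))
      se <- sqrt((n - 1) / n * sum((f_loo - mean(f_loo))^2))
      out[[length(out) + 1L]] <- data.frame(group = g, phase = p,
                                            fraction = f, se = se,
                                            stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
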