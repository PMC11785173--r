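#' @title Consensus non-negative matrix factorization of expression programs
#' @description
#' A cell x gene matrix is factorised as `X ~ U S` with non-negative usages
#' `U` (cell x K) and spectra `S` (K x gene). Repeated factorizations from
#' different seeds are pooled; outlier components are removed by a local
#' density filter; survivors are clustered and their elementwise medians form
#' consensus spectra, against which usages are refit by non-negative least
#' squares. Genes are scaled to unit variance without centering beforehand,
#' preserving non-negativity.
#' @name consensus-nmf
NULL

# Non-negative double SVD initialisation (Boutsidis & Gallopoulos style):
# deterministic given the matrix; small positive jitter seeded per run keeps
# replicate runs distinct.
nndsvd_init <- function(X, k, eps = 1e-9) {
  sv <- svd(X, nu = k, nv = k)
  U <- matrix(0, nrow(X), k); V <- matrix(0, ncol(X), k)
  U[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  V[, 1] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  for (j in seq_len(k)[-1]) {
    u <- sv$u[, j]; v <- sv$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    n_p <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
    n_n <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
    if (n_p >= n_n) {
      scl <- sqrt(sv$d[j] * n_p)
      U[, j] <- scl * up / max(sqrt(sum(up^2)), eps)
      V[, j] <- scl * vp / max(sqrt(sum(vp^2)), eps)
    } else {
      scl <- sqrt(sv$d[j] * n_n)
      U[, j] <- scl * un / max(sqrt(sum(un^2)), eps)
      V[, j] <- scl * vn / max(sqrt(sum(vn^2)), eps)
    }
  }
  list(U = pmax(U, eps), V = pmax(V, eps))
}

# One NMF run by multiplicative updates (Frobenius loss). The first run
# starts from the deterministic non-negative double SVD; later runs start
# from random non-negative matrices scaled to the data. Replicate runs must
# be able to reach different local optima, otherwise the consensus
# stability carries no information about whether k matches the data.
nmf_single <- function(X, k, seed, max_iter = 300L, tol = 1e-6,
                       init = c("random", "nndsvd")) {
  init <- match.arg(init)
  if (init == "nndsvd") {
    ini <- nndsvd_init(X, k)
    U <- ini$U; V <- ini$V
    with_seed(seed, {
      U <- U * matrix(stats::runif(length(U), 0.9, 1.1), nrow(U))
      V <- V * matrix(stats::runif(length(V), 0.9, 1.1), nrow(V))
    })
  } else {
    scl <- sqrt(mean(X) / k)
    with_seed(seed, {
      U <- matrix(scl * stats::rexp(nrow(X) * k), nrow(X), k)
      V <- matrix(scl * stats::rexp(ncol(X) * k), ncol(X), k)
    })
  }
  eps <- 1e-12
  err_prev <- Inf
  for (it in seq_len(max_iter)) {
    V <- V * t((t(U) %*% X)) / (V %*% (t(U) %*% U) + eps)
    U <- U * (X %*% V) / (U %*% (t(V) %*% V) + eps)
    if (it %% 20L == 0L) {
      err <- sum((X - U %*% t(V))^2)
      if (is.finite(err_prev) && abs(err_prev - err) < tol * max(err, 1)) break
      err_prev <- err
    }
  }
  list(usage = U, spectra = t(V))   # spectra: k x gene
}

# mean silhouette over components given a distance matrix and labels
mean_silhouette <- function(D, labels) {
  n <- length(labels)
  if (length(unique(labels)) < 2L) return(NA_real_)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1L) mean(D[i, own & seq_len(n) != i]) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), 0))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Run consensus NMF at a fixed number of programs
#'
#' @param matrix cell x gene non-negative matrix.
#' @param k number of programs.
#' @param n_runs number of replicate factorizations.
#' @param density_threshold components whose mean Euclidean distance to
#'   their `floor(n_runs/3)` nearest pooled neighbours exceeds this are
#'   discarded before clustering (0.5 is the conventional default).
#' @param seed integer seed governing run seeds and the k-means step.
#' @param scale_genes scale genes to unit variance (no centering) first.
#' @return an object of class `program_decomposition`: `loadings`
#'   (gene x K consensus spectra, rows of unit L2 norm across genes per
#'   program), `usages` (cell x K), `k`, `stability` (mean silhouette),
#'   `error` (Frobenius reconstruction error on the scaled matrix),
#'   `n_runs`, `density_threshold`, `n_components_kept`.
#' @export
run_consensus_nmf <- function(matrix, k, n_runs = 30L,
                              density_threshold = 0.5, seed = 7L,
                              scale_genes = TRUE) {
  X <- as.matrix(matrix)
  if (any(X < 0)) stopf("input matrix must be non-negative")
  if (k >= min(dim(X))) stopf("k must be smaller than both matrix dimensions")
  gene_sd <- apply(X, 2, stats::sd)
  gene_sd[gene_sd == 0] <- 1
  if (scale_genes) X <- sweep(X, 2, gene_sd, `/`)

  spectra <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    fit <- nmf_single(X, k, seed = seed * 1000L + r,
                      init = if (r == 1L) "nndsvd" else "random")
    S <- fit$spectra
    S <- S / pmax(sqrt(rowSums(S^2)), 1e-12)      # L2-normalise components
    spectra[[r]] <- S
  }
  pool <- do.call(rbind, spectra)

  D <- as.matrix(stats::dist(pool))
  nn <- max(floor(n_runs / 3), 1L)
  mean_nn_dist <- apply(D, 1, function(d) mean(sort(d)[1L + seq_len(nn)]))
  keep <- mean_nn_dist <= density_threshold
  if (sum(keep) < k)
    stopf("degenerate consensus: only %d components survive the density filter (k = %d)",
          sum(keep), k)
  pool <- pool[keep, , drop = FALSE]
  D <- D[keep, keep, drop = FALSE]

  km <- with_seed(seed + 1L, stats::kmeans(pool, centers = k, nstart = 10L,
                                           iter.max = 100L))
  labels <- km$cluster
  if (any(tabulate(labels, k) == 0L))
    stopf("degenerate consensus: an empty cluster at k = %d", k)
  stability <- mean_silhouette(D, labels)

  consensus <- t(vapply(seq_len(k), function(cl)
    apply(pool[labels == cl, , drop = FALSE], 2, stats::median),
    numeric(ncol(pool))))
  consensus <- consensus / pmax(sqrt(rowSums(consensus^2)), 1e-12)

  # reproducible program numbering: by decreasing cluster size, ties broken
  # by the lexicographic order of the rounded spectrum
  sizes <- tabulate(labels, k)
  key <- apply(round(consensus, 8), 1, paste, collapse = ",")
  ord <- order(-sizes, key)
  consensus <- consensus[ord, , drop = FALSE]

  usages <- t(apply(X, 1, function(row)
    pracma::lsqnonneg(t(consensus), row)$x))
  if (k == 1L) usages <- t(usages)
  err <- sqrt(sum((X - usages %*% consensus)^2))

  loadings <- t(consensus)
  dimnames(loadings) <- list(colnames(matrix), paste0("P", seq_len(k)))
  dimnames(usages) <- list(rownames(matrix), paste0("P", seq_len(k)))
  structure(list(loadings = loadings, usages = usages, k = k,
                 stability = stability, error = err, n_runs = n_runs,
                 density_threshold = density_threshold,
                 n_components_kept = nrow(pool)),
            class = "program_decomposition")
}

#' Stability/error table over candidate numbers of programs
#'
#' Runs [run_consensus_nmf()] at each candidate k and tabulates stability
#' (mean silhouette) against reconstruction error. No k is chosen
#' automatically; the caller inspects the trade-off.
#'
#' @inheritParams run_consensus_nmf
#' @param k_candidates integer vector of k values to try (output is sorted
#'   ascending by k).
#' @return data.frame with `k`, `stability`, `error`, `n_components_kept`,
#'   `status` (`"ok"` or the error message for infeasible k).
#' @export
select_k <- function(matrix, k_candidates, n_runs = 30L,
                     density_threshold = 0.5, seed = 7L) {
  k_candidates <- sort(unique(as.integer(k_candidates)))
  rows <- lapply(k_candidates, function(k) {
    dec <- try(run_consensus_nmf(matrix, k, n_runs, density_threshold, seed),
               silent = TRUE)
    if (inherits(dec, "try-error"))
      data.frame(k = k, stability = NA_real_, error = NA_real_,
                 n_components_kept = NA_integer_,
                 status = conditionMessage(attr(dec, "condition")))
    else
      data.frame(k = k, stability = dec$stability, error = dec$error,
                 n_components_kept = dec$n_components_kept, status = "ok")
  })
  do.call(rbind, rows)
}

#' Top-loading genes of a program
#'
#' @param dec a `program_decomposition` (or any gene x K loadings matrix).
#' @param program program index.
#' @param n number of genes to return.
#' @return character vector of gene ids sorted by loading descending, ties
#'   broken by gene id.
#' @export
top_loading_genes <- function(dec, program, n) {
  L <- if (inherits(dec, "program_decomposition")) dec$loadings else dec
  if (n > nrow(L)) stopf("n (%d) exceeds the %d genes available", n, nrow(L))
  v <- L[, program]
  ids <- rownames(L)
  ids[order(-v, ids)][seq_len(n)]
}
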