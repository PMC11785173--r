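#' Read and write the pipeline's plain-text interchange formats
#'
#' Burden summaries travel as 4+ column TSV (`gene`, `gamma_hat`, `se`,
#' `shet`, plus any posterior columns); cell data as MatrixMarket MTX
#' (genes x cells) with `genes.tsv` and `cells.tsv` sidecars; TF peaks as
#' 10-column ENCODE narrowPeak (strength = -log10 q in column 9, summit
#' offset in column 10); TSSs as 6-column BED (0-based, half-open).
#'
#' @name progtrait-io
NULL

#' @param x data.frame of burden statistics.
#' @param path file path.
#' @rdname progtrait-io
#' @export
write_burden_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname progtrait-io
#' @export
read_burden_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene", "gamma_hat", "se", "shet")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("burden TSV missing columns: %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene)) stopf("burden TSV has duplicated gene ids")
  df
}

#' @param cd a `cell_data` object.
#' @param dir output directory (created if absent).
#' @rdname progtrait-io
#' @export
write_cell_data <- function(cd, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(cd$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(cd$counts), file.path(dir, "genes.tsv"))
  utils::write.table(cd$cells, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname progtrait-io
#' @export
read_cell_data <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- utils::read.table(file.path(dir, "cells.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  dimnames(counts) <- list(genes, cells$cell)
  mito <- grep("^mt", genes, value = TRUE)
  structure(list(counts = counts, cells = cells, genes = genes,
                 mito_genes = mito), class = "cell_data")
}

#' @param peaks data.frame with `tf`, `chrom`, `start`, `end`, `strength`
#'   and optional `summit_offset`.
#' @rdname progtrait-io
#' @export
write_narrowpeak <- function(peaks, path) {
  so <- if ("summit_offset" %in% names(peaks)) peaks$summit_offset else -1L
  np <- data.frame(peaks$chrom, peaks$start, peaks$end,
                   name = paste0(peaks$tf, "_peak", seq_len(nrow(peaks))),
                   score = 0L, strand = ".", signalValue = 0,
                   pValue = -1, qValue = peaks$strength, peak = so)
  utils::write.table(np, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname progtrait-io
#' @export
read_narrowpeak <- function(path) {
  np <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(np) < 10L) stopf("narrowPeak requires 10 columns, found %d", ncol(np))
  if (any(np[[2]] < 0)) stopf("negative start coordinate in narrowPeak")
  data.frame(tf = sub("_peak[0-9]+$", "", np[[4]]), chrom = np[[1]],
             start = np[[2]], end = np[[3]], strength = np[[9]],
             summit_offset = np[[10]], stringsAsFactors = FALSE)
}

#' @param tss data.frame with `chrom`, `start`, `end`, `gene`.
#' @rdname progtrait-io
#' @export
write_tss_bed <- function(tss, path) {
  bed <- data.frame(tss$chrom, tss$start, tss$end, tss$gene,
                    score = if ("score" %in% names(tss)) tss$score else 0L,
                    strand = if ("strand" %in% names(tss)) tss$strand else "+")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname progtrait-io
#' @export
read_tss_bed <- function(path) {
  bed <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 4L) stopf("TSS BED requires >= 4 columns")
  if (any(bed[[2]] < 0)) stopf("negative start coordinate in BED")
  data.frame(chrom = bed[[1]], start = bed[[2]], end = bed[[3]],
             gene = bed[[4]],
             score = if (ncol(bed) >= 5) bed[[5]] else 0L,
             strand = if (ncol(bed) >= 6) bed[[6]] else "+",
             stringsAsFactors = FALSE)
}

#' @param truth a `ground_truth` object.
#' @rdname progtrait-io
#' @export
write_ground_truth_json <- function(truth, path) {
  x <- truth
  x$config <- unclass(x$config)
  x$loadings <- list(values = unname(as.vector(x$loadings)),
                     dim = dim(x$loadings), genes = rownames(x$loadings))
  x$regulator_effects <- list(values = unname(as.vector(x$regulator_effects)),
                              dim = dim(x$regulator_effects))
  # named vectors must become JSON objects, not bare arrays
  for (nm in c("gamma_true", "shet", "program_membership", "regulators",
               "tf_assignments"))
    x[[nm]] <- as.list(x[[nm]])
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname progtrait-io
#' @export
read_ground_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  genes <- x$loadings$genes
  K <- x$loadings$dim[2]
  pn <- paste0("P", seq_len(K))
  x$loadings <- matrix(x$loadings$values, x$loadings$dim[1], K,
                       dimnames = list(genes, pn))
  x$regulator_effects <- matrix(x$regulator_effects$values,
                                x$regulator_effects$dim[1], K,
                                dimnames = list(genes, pn))
  for (nm in c("gamma_true", "shet"))
    x[[nm]] <- stats::setNames(as.numeric(x[[nm]]), genes)
  for (nm in c("program_membership", "regulators", "tf_assignments"))
    x[[nm]] <- stats::setNames(as.integer(unlist(x[[nm]])),
                               names(unlist(x[[nm]])))
  x$config <- structure(x$config, class = "sim_config")
  structure(x, class = "ground_truth")
}
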