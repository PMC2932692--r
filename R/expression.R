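#' Quantile-normalize an expression matrix across samples
#'
#' After normalization every column shares the same marginal distribution:
#' for each rank, all columns take the cross-column mean of their rank-r
#' order statistics, with ties averaged and within-column ordering
#' preserved. Delegates to `limma::normalizeQuantiles`.
#'
#' @param matrix numeric probes x samples matrix (log2 scale), >= 2 columns.
#' @return the normalized matrix.
#' @export
quantile_normalize <- function(matrix) {
  if (!is.matrix(matrix)) matrix <- as.matrix(matrix)
  if (ncol(matrix) < 2L) stop("need at least 2 samples")
  if (anyNA(matrix)) stop("ragged or missing entries are not supported")
  out <- limma::normalizeQuantiles(matrix, ties = TRUE)
  dimnames(out) <- dimnames(matrix)
  out
}

#' Summarize probe-level values into one value per gene and sample
#'
#' Fits the additive model `value ~ gene_effect + sample_effect +
#' probe_effect` to each gene's probes x samples submatrix by median polish
#' (row sweep first, overall effect absorbed into the gene effect) and
#' returns `gene_effect + sample_effect` per sample — the RMA-style
#' summarization step.
#'
#' @param matrix numeric probes x samples matrix (typically
#'   quantile-normalized log2 values).
#' @param probe_gene character vector mapping each row to a gene id.
#' @param eps,maxiter median-polish convergence controls.
#' @return numeric genes x samples matrix of summarized expression values.
#' @export
summarize_gene <- function(matrix, probe_gene, eps = 1e-6, maxiter = 10L) {
  if (!is.matrix(matrix)) matrix <- as.matrix(matrix)
  if (length(probe_gene) != nrow(matrix))
    stop("probe_gene must map every row of the matrix")
  genes <- unique(probe_gene)
  out <- matrix(NA_real_, length(genes), ncol(matrix),
                dimnames = list(genes, colnames(matrix)))
  for (g in genes) {
    sub <- matrix[probe_gene == g, , drop = FALSE]
    if (all(is.na(sub))) next
    if (nrow(sub) == 1L) { out[g, ] <- sub[1, ]; next }
    mp <- suppressWarnings(medpolish(sub, eps = eps, maxiter = maxiter,
                                     trace.iter = FALSE, na.rm = TRUE))
    out[g, ] <- mp$overall + mp$col
  }
  out
}

#' Average summarized expression across samples and z-score across genes
#'
#' @param gene_by_sample numeric genes x samples matrix (e.g. from
#'   [summarize_gene()]).
#' @return named numeric vector of per-gene RNA z-scores (population SD).
#' @export
average_and_zscore <- function(gene_by_sample) {
  if (!is.matrix(gene_by_sample)) gene_by_sample <- as.matrix(gene_by_sample)
  if (ncol(gene_by_sample) < 1L) stop("need at least one sample")
  mu <- rowMeans(gene_by_sample, na.rm = TRUE)
  ok <- is.finite(mu)
  if (sum(ok) < 2L) stop("need at least 2 genes with values")
  z <- rep(NA_real_, length(mu))
  z[ok] <- zscore_standardize(mu[ok])
  setNames(z, rownames(gene_by_sample))
}
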