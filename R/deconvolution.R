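#' @title Cell-type deconvolution covariates
#' @description Estimates CD4+ sub-population proportions from bulk counts by
#'   non-negative least squares of bulk CPM on a single-cell signature, and
#'   selects proportion covariates by the strict >5% mean-proportion rule.
#' @name deconvolution
NULL

cpm <- function(x) sweep(x, 2, colSums(x), "/") * 1e6

#' Build a CPM-scale signature matrix from a labelled single-cell reference
#'
#' Cells are scaled to counts-per-million, then averaged within each label.
#'
#' @param reference gene x cell count matrix.
#' @param labels cell-type label per cell (parallel to columns).
#' @param bulk_genes optional gene ids; the signature is restricted to genes
#'   present in the bulk.
#' @return gene x cell-type signature matrix (CPM scale).
#' @export
buildSignature <- function(reference, labels, bulk_genes = NULL) {
  if (length(labels) != ncol(reference))
    stop("one label per reference cell required")
  z <- cpm(reference)
  types <- unique(labels)
  sig <- vapply(types, function(t)
    rowMeans(z[, labels == t, drop = FALSE]), numeric(nrow(z)))
  colnames(sig) <- types
  if (!is.null(bulk_genes))
    sig <- sig[intersect(rownames(sig), bulk_genes), , drop = FALSE]
  sig
}

#' Estimate cell-type proportions by NNLS
#'
#' Each bulk sample (CPM scale) is regressed on the signature columns by
#' non-negative least squares; coefficients are renormalised to sum to one.
#' Proportions are invariant to global rescaling of a bulk sample. A sample
#' whose coefficients are all zero is assigned uniform proportions with a
#' warning; (near-)collinear signature columns are flagged degenerate.
#'
#' @param bulk gene x sample matrix (counts or CPM) or a
#'   [SummarizedExperiment::SummarizedExperiment].
#' @param signature gene x cell-type matrix from [buildSignature()].
#' @param min_shared_genes required overlap between bulk and signature genes.
#' @return data.frame with `sample_id` and one proportion column per cell
#'   type; rows sum to one.
#' @export
estimateProportions <- function(bulk, signature, min_shared_genes = 50L) {
  x <- exprValues(bulk)
  if (ncol(signature) < 2L) stop("need >= 2 cell types for estimation")
  shared <- intersect(rownames(x), rownames(signature))
  if (length(shared) < min_shared_genes)
    stop("fewer than ", min_shared_genes, " genes shared with the signature")
  S <- signature[shared, , drop = FALSE]
  qs <- qr(S)
  if (qs$rank < ncol(S))
    stop("degenerate signature: collinear cell-type columns")
  y <- cpm(x[shared, , drop = FALSE])
  # joint rescale keeps the coefficients identical but keeps the NNLS
  # active-set iteration well-conditioned on CPM-scale magnitudes
  sc <- mean(S)
  props <- t(apply(y, 2, function(col) {
    b <- pracma::lsqnonneg(S / sc, col / sc)$x
    if (sum(b) == 0) {
      warning("all-zero NNLS coefficients; returning uniform proportions")
      b <- rep(1, ncol(S))
    }
    b / sum(b)
  }))
  colnames(props) <- colnames(S)
  data.frame(sample_id = colnames(x), props, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Select proportion covariates by mean abundance
#'
#' Keeps cell types whose mean proportion across samples is strictly greater
#' than the threshold (default 5%).
#'
#' @param proportions data.frame from [estimateProportions()].
#' @param threshold strict lower bound on the mean proportion.
#' @return character vector of retained cell-type names.
#' @export
selectProportionCovariates <- function(proportions, threshold = 0.05) {
  pcols <- setdiff(names(proportions), "sample_id")
  mu <- vapply(proportions[pcols], mean, numeric(1))
  names(mu)[mu > threshold]
}

#' Append proportion columns to a sample table
#'
#' @param samples sample data.frame with `sample_id`.
#' @param proportions data.frame from [estimateProportions()].
#' @param keep optional subset of cell types (e.g. from
#'   [selectProportionCovariates()]).
#' @return the augmented sample table.
#' @export
appendProportions <- function(samples, proportions, keep = NULL) {
  if (is.null(keep)) keep <- setdiff(names(proportions), "sample_id")
  idx <- match(samples$sample_id, proportions$sample_id)
  if (anyNA(idx)) stop("proportions missing for some samples")
  cbind(samples, proportions[idx, keep, drop = FALSE])
}
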