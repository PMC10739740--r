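#' @title Count QC, normalisation and covariate residualisation
#' @name qc
NULL

#' Filter lowly expressed genes
#'
#' Keeps a gene iff it has at least `min_count` counts in at least
#' `min_samples` samples. Idempotent; gene order preserved.
#'
#' @param se raw-layer [SummarizedExperiment::SummarizedExperiment].
#' @param min_count minimum count per sample (default 5).
#' @param min_samples minimum number of samples reaching it (default 10).
#' @return the filtered experiment.
#' @export
filterGenes <- function(se, min_count = 5L, min_samples = 10L) {
  if (exprLayer(se) != "raw") stop("filterGenes expects the raw count layer")
  x <- exprValues(se)
  keep <- rowSums(x >= min_count) >= min_samples
  if (!any(keep)) stop("no gene passes the count filter")
  se[keep, ]
}

#' Median-of-ratios size factors and log2 transformation
#'
#' Size factors are computed by the median-of-ratios method over genes with
#' all-positive counts (each sample's median ratio to the per-gene geometric
#' mean); when no gene is all-positive the fallback is library size divided
#' by the geometric mean of library sizes. The transformed value is
#' `log2(count / size_factor + 1)`, a variance-reducing transform on the
#' normalised scale.
#'
#' @param se raw-layer experiment (typically after [filterGenes()]).
#' @return a transformed-layer experiment with `size_factor` added to
#'   `colData`.
#' @export
normaliseTransform <- function(se) {
  if (exprLayer(se) != "raw")
    stop("normaliseTransform expects the raw count layer")
  x <- exprValues(se)
  if (any(colSums(x) == 0)) stop("sample(s) with zero total count")
  allpos <- rowSums(x > 0) == ncol(x)
  if (any(allpos)) {
    lg <- rowMeans(log(x[allpos, , drop = FALSE]))
    sf <- apply(x[allpos, , drop = FALSE], 2,
                function(col) exp(median(log(col) - lg)))
  } else {
    ls <- colSums(x)
    sf <- ls / exp(mean(log(ls)))
  }
  y <- log2(sweep(x, 2, sf, "/") + 1)
  samples <- as.data.frame(SummarizedExperiment::colData(se))
  samples$size_factor <- as.numeric(sf)
  out <- makeExpressionExperiment(y, samples, layer = "transformed")
  out
}

singletonMergeHeights <- function(hc, n) {
  # height at which each original observation is first merged
  h <- numeric(n)
  for (k in seq_len(nrow(hc$merge))) {
    for (side in 1:2) {
      v <- hc$merge[k, side]
      if (v < 0) h[-v] <- hc$height[k]
    }
  }
  h
}

#' Flag outlier samples by hierarchical clustering merge height
#'
#' Samples are clustered by average linkage on Euclidean distance over the
#' `top_expressed` most expressed genes (ranked by mean). A sample is flagged
#' when the height at which it first merges into the tree exceeds
#' `mean + height_factor * sd` of all singleton merge heights.
#'
#' @param se transformed-layer experiment.
#' @param top_expressed number of top genes by mean expression (default 100).
#' @param height_factor SD multiplier of the flag threshold (default 3).
#' @return character vector of flagged sample ids (possibly empty). Flagged
#'   samples are reported, never dropped automatically.
#' @export
detectOutlierSamples <- function(se, top_expressed = 100L,
                                 height_factor = 3) {
  if (exprLayer(se) != "transformed")
    stop("detectOutlierSamples expects the transformed layer")
  x <- exprValues(se)
  if (ncol(x) < 3L) stop("need at least 3 samples for outlier detection")
  top <- head(order(-rowMeans(x)), min(top_expressed, nrow(x)))
  d <- dist(t(x[top, , drop = FALSE]))
  hc <- hclust(d, method = "average")
  h <- singletonMergeHeights(hc, ncol(x))
  thr <- mean(h) + height_factor * sd(h)
  if (!is.finite(thr)) return(character(0))
  colnames(x)[h > thr]
}

#' Keep the most variable genes
#'
#' Retains the top `ceil(quantile * G)` genes by variance; ties are broken by
#' gene id order (lexicographic), so the selection is deterministic.
#'
#' @param se transformed-layer experiment.
#' @param quantile fraction of genes kept (default 0.75).
#' @return the reduced experiment, original gene order preserved.
#' @export
selectVariableGenes <- function(se, quantile = 0.75) {
  if (quantile <= 0 || quantile > 1) stop("quantile must lie in (0, 1]")
  x <- exprValues(se)
  v <- apply(x, 1, var)
  nkeep <- ceiling(quantile * nrow(x))
  ord <- order(-v, rownames(x))
  keep <- sort(ord[seq_len(nkeep)])
  se[keep, ]
}

#' Regress covariates out of each gene
#'
#' Per gene, ordinary least squares of expression on an intercept plus the
#' requested covariate columns of `colData` (categorical covariates are
#' one-hot encoded with the first level dropped). Returns residuals plus the
#' fitted intercept, so the expression level is preserved while every
#' covariate direction is removed exactly (OLS residuals are orthogonal to
#' the design at machine precision).
#'
#' @param se transformed-layer experiment.
#' @param covariates character vector of `colData` column names.
#' @return a residualised-layer experiment.
#' @export
residualise <- function(se, covariates) {
  x <- exprValues(se)
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  miss <- setdiff(covariates, names(cd))
  if (length(miss)) stop("covariate column(s) not in sample table: ",
                         paste(miss, collapse = ", "))
  df <- cd[, covariates, drop = FALSE]
  for (nm in names(df))
    if (is.character(df[[nm]]) || is.logical(df[[nm]]))
      df[[nm]] <- factor(df[[nm]])
  X <- stats::model.matrix(~ ., data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- lm.fit(X, t(x))
  res <- t(fit$residuals) + matrix(fit$coefficients["(Intercept)", ],
                                   nrow(x), ncol(x), byrow = FALSE)
  dimnames(res) <- dimnames(x)
  makeExpressionExperiment(res, cd, layer = "residualised")
}
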