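#' @title Signed-hybrid weighted co-expression network
#' @description Builds the weighted network from gene-gene Pearson
#'   correlations: a signed-hybrid adjacency raises positive correlations to
#'   the soft-threshold power and zeroes negative ones, the topological
#'   overlap measure (TOM) rewards shared neighbourhoods, and modules are the
#'   branches of an average-linkage tree on 1 - TOM. Module eigengenes,
#'   module membership (kME) and gene significance summarise the result.
#' @name coexpression
NULL

#' Network construction parameters
#'
#' @param beta soft-threshold power (positive integer, default 6).
#' @param min_module_size smallest retained cluster (default 30).
#' @param cut_height static tree-cut height; `NULL` uses 0.995 of the
#'   maximum merge height.
#' @param merge_cor eigengene correlation above which modules merge
#'   (default 0.75).
#' @param kme_reassign_min minimum kME for rescuing an unassigned gene into
#'   its best-correlated module (default 0.3).
#' @param scale_free_target_r2 model-fit target for soft-threshold selection
#'   (default 0.80).
#' @return a validated parameter list.
#' @export
networkParams <- function(beta = 6L, min_module_size = 30L,
                          cut_height = NULL, merge_cor = 0.75,
                          kme_reassign_min = 0.3,
                          scale_free_target_r2 = 0.80) {
  if (beta < 1) stop("beta must be >= 1")
  if (!is.null(cut_height) && (cut_height <= 0 || cut_height > 1))
    stop("cut_height must lie in (0, 1]")
  list(beta = beta, network_type = "signed hybrid",
       min_module_size = as.integer(min_module_size),
       cut_height = cut_height, merge_cor = merge_cor,
       kme_reassign_min = kme_reassign_min,
       scale_free_target_r2 = scale_free_target_r2)
}

#' Signed-hybrid adjacency
#'
#' `a_ij = cor_ij ^ beta` for positive correlations, 0 otherwise; the
#' diagonal is set to 0 so connectivity sums exclude self-adjacency.
#'
#' @param corr symmetric gene x gene correlation matrix with entries in
#'   `[-1, 1]`.
#' @param beta soft-threshold power.
#' @return adjacency matrix with entries in `[0, 1]`.
#' @export
signedHybridAdjacency <- function(corr, beta = 6L) {
  if (!isSymmetric(unname(corr), tol = 1e-8))
    stop("correlation matrix must be symmetric")
  if (any(corr < -1 - 1e-8 | corr > 1 + 1e-8))
    stop("correlations must lie in [-1, 1]")
  a <- ifelse(corr > 0, pmin(corr, 1)^beta, 0)
  diag(a) <- 0
  a
}

#' Soft-threshold selection by scale-free model fit
#'
#' For each candidate power the connectivities `k_i = sum_j a_ij` are binned
#' into 10 logarithmic bins (empty bins and zero-connectivity genes
#' dropped) and `log10 p(k)` is regressed on `log10 k`; the fit R-squared
#' counts only when the slope is negative. The chosen power is the smallest
#' candidate reaching `target_r2`, else the argmax R-squared with a warning.
#'
#' @param x transformed/residualised experiment or gene x sample matrix.
#' @param candidates candidate powers (default 1:20).
#' @param target_r2 required model fit (default 0.80).
#' @return list (`SoftThresholdReport`): `table` with `beta`, `r2`,
#'   `slope`, `mean_k`; `chosen` power.
#' @export
pickSoftThreshold <- function(x, candidates = 1:20, target_r2 = 0.80) {
  xm <- exprValues(x)
  cc <- cor(t(xm))
  rows <- lapply(candidates, function(b) {
    a <- signedHybridAdjacency(cc, b)
    k <- rowSums(a)
    fit <- scaleFreeFit(k)
    data.frame(beta = b, r2 = fit$r2, slope = fit$slope, mean_k = mean(k))
  })
  tab <- do.call(rbind, rows)
  ok <- which(tab$r2 >= target_r2)
  if (length(ok)) chosen <- tab$beta[ok[1]]
  else {
    chosen <- tab$beta[which.max(tab$r2)]
    warning("no candidate reaches the scale-free fit target; ",
            "using the best-fitting power ", chosen)
  }
  list(table = tab, chosen = chosen, target_r2 = target_r2)
}

scaleFreeFit <- function(k, nbins = 10L) {
  k <- k[k > 0]
  if (length(unique(k)) < 3L) return(list(r2 = 0, slope = NA_real_))
  lk <- log10(k)
  br <- seq(min(lk), max(lk), length.out = nbins + 1L)
  bin <- cut(lk, br, include.lowest = TRUE)
  p <- tabulate(bin, nbins = nbins) / length(lk)
  km <- tapply(lk, bin, mean)
  keep <- p > 0 & !is.na(km)
  if (sum(keep) < 3L) return(list(r2 = 0, slope = NA_real_))
  fit <- stats::lm.fit(cbind(1, km[keep]), log10(p[keep]))
  slope <- fit$coefficients[2]
  ssr <- sum(fit$residuals^2)
  sst <- sum((log10(p[keep]) - mean(log10(p[keep])))^2)
  r2 <- if (sst == 0) 0 else 1 - ssr / sst
  if (is.na(slope) || slope >= 0) r2 <- 0
  list(r2 = max(0, r2), slope = unname(slope))
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj`; the diagonal is 1.
#'
#' @param adjacency symmetric adjacency with zero diagonal, entries in
#'   `[0, 1]`.
#' @return TOM similarity matrix (symmetric, entries in `[0, 1]`).
#' @export
tomSimilarity <- function(adjacency) {
  if (!isSymmetric(unname(adjacency), tol = 1e-10))
    stop("adjacency must be symmetric")
  a <- adjacency
  diag(a) <- 0
  l <- a %*% a
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect modules on the TOM dissimilarity tree
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, static cut at
#' `cut_height` (default 0.995 of the maximum merge height), clusters below
#' `min_module_size` sent to label 0, labels renumbered by decreasing size;
#' a second pass reassigns each unassigned gene to the module with the
#' highest kME when that kME exceeds `kme_reassign_min`.
#'
#' @param tom TOM similarity matrix.
#' @param x expression (experiment or gene x sample matrix) used for the
#'   kME rescue pass; genes must match the TOM rows.
#' @param params a [networkParams()] list.
#' @return a [ModuleSet] with labels and eigengenes.
#' @export
detectModules <- function(tom, x, params = networkParams()) {
  xm <- exprValues(x)
  stopifnot(identical(rownames(tom), rownames(xm)))
  d <- as.dist(1 - tom)
  hc <- hclust(d, method = "average")
  h <- if (is.null(params$cut_height)) 0.995 * max(hc$height)
       else params$cut_height
  raw <- cutree(hc, h = h)
  sz <- table(raw)
  keep <- names(sz)[sz >= params$min_module_size]
  labels <- integer(length(raw))
  if (length(keep)) {
    keep <- keep[order(-sz[keep])]
    for (i in seq_along(keep)) labels[raw == as.integer(keep[i])] <- i
  }
  names(labels) <- rownames(tom)
  if (any(labels > 0L) && any(labels == 0L)) {
    me <- moduleEigengenes(xm, labels)
    kme <- cor(t(xm), me)
    un <- which(labels == 0L)
    best <- max.col(kme[un, , drop = FALSE], ties.method = "first")
    bestv <- kme[cbind(un, best)]
    resc <- bestv > params$kme_reassign_min
    labels[un[resc]] <- best[resc]
  }
  me <- if (any(labels > 0L)) moduleEigengenes(xm, labels)
        else matrix(numeric(0), ncol(xm), 0,
                    dimnames = list(colnames(xm), NULL))
  ModuleSet(rownames(xm), labels, eigengenes = me)
}

#' Module eigengenes
#'
#' Per module, genes are standardised (mean 0, SD 1 across samples) and the
#' eigengene is the first right singular vector of the gene x sample block:
#' unit norm, sign-oriented so its correlation with the module's mean
#' standardised profile is positive.
#'
#' @param x expression (experiment or gene x sample matrix).
#' @param labels integer module label per gene (0 = unassigned, skipped).
#' @return samples x modules matrix with columns `ME<k>`.
#' @export
moduleEigengenes <- function(x, labels) {
  xm <- exprValues(x)
  mods <- sort(unique(labels[labels > 0L]))
  out <- matrix(NA_real_, ncol(xm), length(mods),
                dimnames = list(colnames(xm), sprintf("ME%d", mods)))
  for (i in seq_along(mods)) {
    idx <- which(labels == mods[i])
    if (!length(idx)) { warning("module of size 0 skipped"); next }
    xb <- xm[idx, , drop = FALSE]
    xs <- t(scale(t(xb)))
    xs[is.nan(xs)] <- 0
    v <- svd(xs, nu = 0, nv = 1)$v[, 1]
    mprof <- colMeans(xs)
    if (sum(v * mprof) < 0) v <- -v
    out[, i] <- v
  }
  out
}

#' Module membership (kME)
#'
#' Pearson correlation of each gene's expression with each module eigengene.
#'
#' @param x expression (experiment or gene x sample matrix).
#' @param eigengenes samples x modules matrix.
#' @return genes x modules correlation matrix.
#' @export
moduleMembership <- function(x, eigengenes) {
  xm <- exprValues(x)
  cor(t(xm), eigengenes)
}

#' Gene significance
#'
#' Pearson correlation of each gene's expression with the binary phenotype
#' coded 0/1.
#'
#' @param x expression (experiment or gene x sample matrix).
#' @param phenotype 0/1 vector, one entry per sample.
#' @return named numeric vector of per-gene correlations.
#' @export
geneSignificance <- function(x, phenotype) {
  xm <- exprValues(x)
  if (length(phenotype) != ncol(xm))
    stop("phenotype length must equal the number of samples")
  drop(cor(t(xm), as.numeric(phenotype)))
}

#' Merge highly correlated modules
#'
#' Iteratively merges the module pair with the highest eigengene correlation
#' while any pair exceeds `merge_cor`, recomputing eigengenes after each
#' merge. Idempotent: a second call is a no-op.
#'
#' @param x expression (experiment or gene x sample matrix).
#' @param mset a [ModuleSet] (or named label vector).
#' @param merge_cor correlation threshold (default 0.75).
#' @return a [ModuleSet] with merged, size-ranked labels and fresh
#'   eigengenes.
#' @export
mergeModules <- function(x, mset, merge_cor = 0.75) {
  xm <- exprValues(x)
  labels <- if (is(mset, "ModuleSet")) moduleLabels(mset) else mset
  repeat {
    mods <- sort(unique(labels[labels > 0L]))
    if (length(mods) < 2L) break
    me <- moduleEigengenes(xm, labels)
    cc <- cor(me)
    diag(cc) <- -Inf
    mx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (cc[mx[1], mx[2]] <= merge_cor) break
    from <- mods[max(mx)]; to <- mods[min(mx)]
    labels[labels == from] <- to
  }
  # renumber by decreasing size
  mods <- sort(unique(labels[labels > 0L]))
  if (length(mods)) {
    sz <- vapply(mods, function(m) sum(labels == m), integer(1))
    remap <- setNames(order(order(-sz)), mods)
    labels[labels > 0L] <- remap[as.character(labels[labels > 0L])]
  }
  me <- if (length(mods)) moduleEigengenes(xm, labels)
        else matrix(numeric(0), ncol(xm), 0,
                    dimnames = list(colnames(xm), NULL))
  ModuleSet(names(labels), labels, eigengenes = me)
}

#' Full network run: correlation to annotated ModuleSet
#'
#' Convenience wrapper chaining Pearson correlation, signed-hybrid
#' adjacency, TOM, module detection, merging, eigengenes, kME and GS.
#'
#' @param x transformed/residualised experiment or gene x sample matrix.
#' @param phenotype 0/1 vector per sample (for gene significance).
#' @param params a [networkParams()] list.
#' @return a [ModuleSet] with labels, eigengenes, membership and
#'   significance filled in.
#' @export
buildNetwork <- function(x, phenotype = NULL, params = networkParams()) {
  xm <- exprValues(x)
  cc <- cor(t(xm))
  a <- signedHybridAdjacency(cc, params$beta)
  tom <- tomSimilarity(a)
  ms <- detectModules(tom, xm, params)
  ms <- mergeModules(xm, ms, params$merge_cor)
  mm <- if (ncol(ms@eigengenes)) moduleMembership(xm, ms@eigengenes)
        else matrix(numeric(0), nrow(xm), 0)
  gs <- if (!is.null(phenotype)) geneSignificance(xm, phenotype)
        else rep(NA_real_, nrow(xm))
  new("ModuleSet", genes = ms@genes, labels = ms@labels,
      eigengenes = ms@eigengenes, membership = mm,
      significance = setNames(as.numeric(gs), rownames(xm)),
      assocModules = integer(0))
}
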