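#' @title Eigengene-phenotype association and group comparisons
#' @name association
NULL

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR control: `q_(i) = min_(j>=i) p_(j) * m / j`, capped at 1.
#' Delegates to [stats::p.adjust()].
#'
#' @param p numeric vector of p-values (NA allowed; preserved).
#' @return vector of q-values, same order as input.
#' @export
bhFDR <- function(p) p.adjust(p, method = "BH")

#' Test module eigengenes for phenotype association
#'
#' One logistic regression per module: `logit P(case) = b0 + b1 * ME +
#' covariates`, Wald test on `b1`, BH FDR across modules. Perfect (or
#' quasi-perfect) separation is detected and the module flagged
#' non-estimable instead of reporting a divergent estimate.
#'
#' @param eigengenes samples x modules matrix (columns `ME<k>`).
#' @param samples sample data.frame with a binary `phenotype` column
#'   (1 = case) and any covariate columns.
#' @param covariates character vector of covariate column names (may be
#'   empty).
#' @param fdr_level FDR threshold for the `significant` flag (default 0.20).
#' @return data.frame with `module`, `beta`, `se`, `z`, `p`, `q`,
#'   `significant`, `estimable`.
#' @export
associateModules <- function(eigengenes, samples, covariates = character(0),
                             fdr_level = 0.20) {
  y <- samples$phenotype
  if (is.null(y) || !all(y %in% c(0, 1)))
    stop("phenotype must be binary 0/1")
  if (nrow(eigengenes) != nrow(samples))
    stop("eigengenes and samples disagree on sample count")
  miss <- setdiff(covariates, names(samples))
  if (length(miss)) stop("covariate column(s) missing: ",
                         paste(miss, collapse = ", "))
  if (!ncol(eigengenes))
    return(data.frame(module = character(0), beta = numeric(0),
                      se = numeric(0), z = numeric(0), p = numeric(0),
                      q = numeric(0), significant = logical(0),
                      estimable = logical(0)))
  rows <- lapply(colnames(eigengenes), function(m) {
    df <- data.frame(y = y, ME = eigengenes[, m],
                     samples[, covariates, drop = FALSE])
    fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
    sm <- summary(fit)$coefficients
    b <- sm["ME", "Estimate"]; s <- sm["ME", "Std. Error"]
    # (quasi-)separation: degenerate fitted probabilities together with a
    # divergent estimate or exploding standard error
    degenerate <- any(fit$fitted.values > 1 - 1e-8 |
                        fit$fitted.values < 1e-8) || !fit$converged
    estimable <- !(degenerate && (abs(b) > 15 || s > 50))
    if (!estimable) {
      data.frame(module = m, beta = NA_real_, se = NA_real_, z = NA_real_,
                 p = NA_real_, estimable = FALSE)
    } else {
      z <- b / s
      data.frame(module = m, beta = b, se = s, z = z,
                 p = 2 * pnorm(-abs(z)), estimable = TRUE)
    }
  })
  out <- do.call(rbind, rows)
  out$q <- bhFDR(out$p)
  out$significant <- !is.na(out$q) & out$q < fdr_level
  rownames(out) <- NULL
  out[, c("module", "beta", "se", "z", "p", "q", "significant", "estimable")]
}

expectedCounts <- function(m) outer(rowSums(m), colSums(m)) / sum(m)

#' Group-comparison tests for a subject-characteristics table
#'
#' Categorical variables are supplied as 2x2 count matrices (group x level);
#' when any expected cell count is below 5 a two-sided Fisher's exact test
#' is used, otherwise a two-sided Pearson chi-squared test WITHOUT
#' continuity correction. Numeric variables are supplied as raw values plus
#' a group indicator and tested with the two-sided Wilcoxon rank-sum test
#' under the normal approximation with tie correction.
#'
#' @param variables named list; each element is either a 2x2 numeric matrix
#'   of counts or a list with `values` (numeric) and `group` (two-level).
#' @return data.frame with `variable`, `test` and `p`.
#' @export
compareGroups <- function(variables) {
  rows <- lapply(names(variables), function(nm) {
    v <- variables[[nm]]
    if (is.matrix(v)) {
      if (!all(dim(v) == c(2L, 2L))) stop(nm, ": expected a 2x2 count matrix")
      if (any(v < 0)) stop(nm, ": negative counts")
      if (any(expectedCounts(v) < 5)) {
        p <- fisher.test(v)$p.value
        test <- "fisher"
      } else {
        p <- chisq.test(v, correct = FALSE)$p.value
        test <- "chisq"
      }
    } else {
      g <- factor(v$group)
      if (nlevels(g) != 2L) stop(nm, ": need exactly two groups")
      p <- wilcox.test(v$values[g == levels(g)[1]],
                       v$values[g == levels(g)[2]],
                       exact = FALSE, correct = FALSE)$p.value
      test <- "wilcoxon"
    }
    data.frame(variable = nm, test = test, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
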