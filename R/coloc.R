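#' @title Bayesian colocalisation via Wakefield approximate Bayes factors
#' @description Tests whether a GWAS trait and an eQTL share a single causal
#'   variant within a region. Per SNP and trait, the approximate Bayes
#'   factor compares H1 (true effect ~ N(0, W)) with H0 (no effect); the
#'   five regional hypotheses (no association, trait-1 only, trait-2 only,
#'   two distinct causal SNPs, one shared causal SNP) are scored by summing
#'   ABFs over causal-SNP configurations in log space and weighting by the
#'   per-SNP priors p1, p2, p12.
#' @name coloc
NULL

#' Colocalisation priors
#'
#' @param p1,p2 prior probability that a SNP is causal for trait 1 / trait 2
#'   only (defaults 1e-4).
#' @param p12 prior probability of being causal for both (default 1e-5).
#' @param sd_quant,sd_cc prior effect SD W^0.5 for quantitative traits
#'   (0.15) and case-control traits on the log-odds scale (0.20).
#' @return a validated prior list.
#' @export
colocPriors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                        sd_quant = 0.15, sd_cc = 0.20) {
  if (any(c(p1, p2, p12) <= 0)) stop("priors must be > 0")
  if (p1 + p2 + p12 >= 1) stop("p1 + p2 + p12 must be < 1")
  list(p1 = p1, p2 = p2, p12 = p12, sd_quant = sd_quant, sd_cc = sd_cc)
}

#' Log Wakefield approximate Bayes factor
#'
#' With `z = beta/se`, `V = se^2` and shrinkage `r = W/(V + W)`:
#' `log ABF = 0.5 * log(1 - r) + z^2 * r / 2`.
#'
#' @param beta,se effect estimate and standard error (vectorised).
#' @param W prior variance of the true effect (e.g. `0.15^2`).
#' @return vector of log ABFs.
#' @export
logABF <- function(beta, se, W) {
  z <- beta / se
  V <- se^2
  r <- W / (V + W)
  0.5 * log(1 - r) + z^2 * r / 2
}

logSumExp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

logDiffExp <- function(a, b) {
  # log(exp(a) - exp(b)) for a >= b, clamped at -Inf
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Harmonise two summary-statistics regions
#'
#' Intersects on SNP id; where the effect/other alleles are swapped between
#' the datasets the second beta is negated; strand-ambiguous palindromic
#' (A/T, C/G) SNPs are dropped with a logged count; SNPs whose alleles
#' cannot be reconciled are dropped.
#'
#' @param gwas,eqtl summary-statistic data.frames
#'   (`snp chr pos a1 a2 beta se maf n`).
#' @param min_snps minimum surviving SNPs (default 50); below it the region
#'   is skipped (returns `NULL` with a warning).
#' @return list with harmonised `gwas` and `eqtl` (row-aligned), `n_flipped`
#'   and `n_palindromic_dropped`, or `NULL`.
#' @export
harmoniseSumstats <- function(gwas, eqtl, min_snps = 50L) {
  validateSummaryStats(gwas); validateSummaryStats(eqtl)
  common <- intersect(gwas$snp, eqtl$snp)
  g <- gwas[match(common, gwas$snp), , drop = FALSE]
  e <- eqtl[match(common, eqtl$snp), , drop = FALSE]
  pal <- function(a, b) (a == "A" & b == "T") | (a == "T" & b == "A") |
                        (a == "C" & b == "G") | (a == "G" & b == "C")
  isPal <- pal(g$a1, g$a2) | pal(e$a1, e$a2)
  same <- g$a1 == e$a1 & g$a2 == e$a2
  swap <- g$a1 == e$a2 & g$a2 == e$a1
  keep <- !isPal & (same | swap)
  nPal <- sum(isPal)
  g <- g[keep, , drop = FALSE]; e <- e[keep, , drop = FALSE]
  flip <- swap[keep]
  e$beta[flip] <- -e$beta[flip]
  e$a1[flip] <- g$a1[flip]; e$a2[flip] <- g$a2[flip]
  if (nrow(g) < min_snps) {
    warning(sprintf("region skipped: only %d SNPs survive harmonisation (min %d)",
                    nrow(g), min_snps))
    return(NULL)
  }
  rownames(g) <- rownames(e) <- NULL
  attr(g, "trait_type") <- attr(gwas, "trait_type")
  attr(e, "trait_type") <- attr(eqtl, "trait_type")
  list(gwas = g, eqtl = e, n_flipped = sum(flip),
       n_palindromic_dropped = nPal)
}

traitW <- function(stats, priors) {
  tt <- attr(stats, "trait_type")
  if (identical(tt, "cc")) priors$sd_cc^2 else priors$sd_quant^2
}

#' Colocalisation posterior probabilities for a harmonised region
#'
#' Accumulates per-hypothesis evidence in log space (log-sum-exp):
#' `S1 = sum_i ABF1_i`, `S2 = sum_i ABF2_i`, `S12 = sum_i ABF1_i ABF2_i`,
#' `S3 = S1 S2 - S12`; the unnormalised posteriors
#' `(1, p1 S1, p2 S2, p1 p2 S3, p12 S12)` are normalised to PP0-PP4.
#' Outputs stay finite for |z| up to at least 50.
#'
#' @param region list from [harmoniseSumstats()] (or any list with
#'   row-aligned `gwas` and `eqtl`).
#' @param priors a [colocPriors()] list.
#' @return list (`ColocResult`): `n_snps`, `pp` (named PP0..PP4 vector,
#'   summing to one), `evidence` (PP4 > 0.5).
#' @export
colocABF <- function(region, priors = colocPriors()) {
  g <- region$gwas; e <- region$eqtl
  stopifnot(identical(g$snp, e$snp))
  l1 <- logABF(g$beta, g$se, traitW(g, priors))
  l2 <- logABF(e$beta, e$se, traitW(e, priors))
  lS1 <- logSumExp(l1)
  lS2 <- logSumExp(l2)
  lS12 <- logSumExp(l1 + l2)
  lS3 <- logDiffExp(lS1 + lS2, lS12)   # sum over i != j
  lh <- c(
    PP0 = 0,
    PP1 = log(priors$p1) + lS1,
    PP2 = log(priors$p2) + lS2,
    PP3 = log(priors$p1) + log(priors$p2) + lS3,
    PP4 = log(priors$p12) + lS12
  )
  pp <- exp(lh - logSumExp(lh))
  list(n_snps = nrow(g), pp = pp, evidence = unname(pp["PP4"] > 0.5))
}

#' Build cis regions around module genes
#'
#' One region per gene: gene body plus/minus `window`, clipped at zero;
#' regions without any SNP are skipped.
#'
#' @param genes [GenomicRanges::GRanges] gene models (named by gene id).
#' @param stats summary-statistic data.frame providing SNP positions.
#' @param window cis window in bp (default 1e6).
#' @return named list per gene: `chr`, `start`, `end`, `snps` (ids in the
#'   window).
#' @export
buildRegions <- function(genes, stats, window = 1e6) {
  validateSummaryStats(stats)
  out <- list()
  for (i in seq_along(genes)) {
    gid <- names(genes)[i]
    chr <- as.character(GenomicRanges::seqnames(genes)[i])
    lo <- max(0L, GenomicRanges::start(genes)[i] - window)
    hi <- GenomicRanges::end(genes)[i] + window
    sel <- stats$chr == chr & stats$pos >= lo & stats$pos <= hi
    if (!any(sel)) next
    out[[gid]] <- list(chr = chr, start = lo, end = hi,
                       snps = stats$snp[sel])
  }
  out
}
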