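#' @title Master-regulator identification in the PPI network
#' @description Builds the "top gene" set (colocalisation evidence OR joint
#'   top-decile of module membership and gene significance), recombines
#'   STRING-style channel scores with the redundant channels excluded,
#'   identifies the hub protein by induced-subgraph degree, and assesses it
#'   with a max-degree permutation null over random gene sets of the same
#'   size.
#' @name master_regulator
NULL

#' Top-gene selection configuration
#'
#' @param pp4_threshold colocalisation evidence cutoff (default 0.5).
#' @param mm_quantile,gs_quantile top-quantile cutoffs for module membership
#'   and (absolute) gene significance (defaults 0.90).
#' @param channel_exclusions evidence channels removed before score
#'   recombination; defaults to co-expression, neighbourhood and fusion,
#'   which are redundant with a network already built from co-expression.
#' @param combined_score_min medium-confidence combined-score floor (0.4).
#' @param prior random-interaction prior used by the score integration
#'   (0.041).
#' @param n_permutations permutation draws (default 10000, minimum 100).
#' @param seed RNG seed for the permutation test.
#' @param operator `"union"` (default) or `"intersect"`: how the
#'   colocalisation list is combined with the MM/GS top-decile list.
#' @return a validated configuration list.
#' @export
topGeneConfig <- function(pp4_threshold = 0.5, mm_quantile = 0.90,
                          gs_quantile = 0.90,
                          channel_exclusions = c("coexpression",
                                                 "neighbourhood", "fusion"),
                          combined_score_min = 0.4, prior = 0.041,
                          n_permutations = 10000L, seed = 1L,
                          operator = c("union", "intersect")) {
  if (mm_quantile < 0 || mm_quantile >= 1 || gs_quantile < 0 ||
      gs_quantile >= 1) stop("quantiles must lie in [0, 1)")
  if (n_permutations < 100L) stop("n_permutations must be >= 100")
  list(pp4_threshold = pp4_threshold, mm_quantile = mm_quantile,
       gs_quantile = gs_quantile, channel_exclusions = channel_exclusions,
       combined_score_min = combined_score_min, prior = prior,
       n_permutations = as.integer(n_permutations), seed = as.integer(seed),
       operator = match.arg(operator))
}

#' Build the top phenotype-gene set
#'
#' `set = {g : PP4_g >= threshold} OP {g : MM_g(own module) >= Q(mm_quantile)
#' of own-module MM AND |GS_g| >= Q(gs_quantile) of |GS| over the combined
#' associated-module genes}`, with OP = union by default. MM quantiles are
#' computed within each gene's own module; GS quantiles over the combined
#' associated-module genes on the absolute value.
#'
#' @param coloc_pp4 named numeric vector of per-gene PP4 values (genes
#'   without colocalisation results may be absent).
#' @param mset a [ModuleSet] with membership and significance filled and
#'   `assocModules` set (see [associateModules()]).
#' @param cfg a [topGeneConfig()] list.
#' @return data.frame with `gene` and logical provenance columns `coloc`,
#'   `mm_gs`.
#' @export
buildTopGeneSet <- function(coloc_pp4, mset, cfg = topGeneConfig()) {
  am <- associatedModules(mset)
  if (!length(am)) stop("no phenotype-associated modules recorded")
  genes <- moduleGenes(mset, am)
  labels <- moduleLabels(mset)[genes]
  colocGenes <- names(coloc_pp4)[coloc_pp4 >= cfg$pp4_threshold]
  colocGenes <- intersect(colocGenes, genes)

  gs <- abs(mset@significance[genes])
  gsCut <- quantile(gs, cfg$gs_quantile, na.rm = TRUE, names = FALSE)
  topGS <- genes[!is.na(gs) & gs >= gsCut]

  topMM <- character(0)
  for (m in am) {
    mg <- genes[labels == m]
    mm <- mset@membership[mg, sprintf("ME%d", m)]
    mmCut <- quantile(mm, cfg$mm_quantile, na.rm = TRUE, names = FALSE)
    topMM <- c(topMM, mg[!is.na(mm) & mm >= mmCut])
  }
  mmgs <- intersect(topMM, topGS)
  sel <- if (cfg$operator == "union") union(colocGenes, mmgs)
         else intersect(colocGenes, mmgs)
  if (!length(sel))
    return(data.frame(gene = character(0), coloc = logical(0),
                      mm_gs = logical(0)))
  data.frame(gene = sort(sel),
             coloc = sort(sel) %in% colocGenes,
             mm_gs = sort(sel) %in% mmgs,
             stringsAsFactors = FALSE)
}

#' Combine per-channel scores into one confidence score
#'
#' Prior-corrected noisy-OR, the STRING-style integration: each channel is
#' corrected as `s' = max(0, (s - prior) / (1 - prior))`, the corrected
#' scores combine as `1 - prod(1 - s')`, and the prior is added back as
#' `final = combined * (1 - prior) + prior`. On a single active channel the
#' round-trip is the identity.
#'
#' @param scores edge x channel numeric matrix.
#' @param prior random-interaction prior (default 0.041).
#' @return numeric vector of combined scores.
#' @export
combineChannelScores <- function(scores, prior = 0.041) {
  if (!nrow(scores)) return(numeric(0))
  sp <- (scores - prior) / (1 - prior)
  sp[sp < 0] <- 0
  comb <- 1 - apply(1 - sp, 1, prod)
  comb * (1 - prior) + prior
}

#' Recombine edge scores with evidence channels excluded
#'
#' Recomputes each edge's combined score from the non-excluded channels and
#' drops edges below the confidence floor.
#'
#' @param network a [PPINetwork].
#' @param exclusions channel names to drop.
#' @param prior random-interaction prior (default 0.041).
#' @param combined_score_min confidence floor (default 0.4; set 0 to keep
#'   all edges).
#' @return a [PPINetwork] with updated `combined` and filtered edges.
#' @export
recombineScores <- function(network,
                            exclusions = c("coexpression", "neighbourhood",
                                           "fusion"),
                            prior = 0.041, combined_score_min = 0.4) {
  ed <- ppiEdges(network)
  keepCh <- setdiff(ppiChannels(), exclusions)
  if (!length(keepCh)) {
    ed$combined <- rep(prior, nrow(ed))
  } else {
    ed$combined <- combineChannelScores(
      as.matrix(ed[, keepCh, drop = FALSE]), prior)
  }
  ed <- ed[ed$combined >= combined_score_min, , drop = FALSE]
  rownames(ed) <- NULL
  PPINetwork(ppiNodes(network), ed)
}

induceDegrees <- function(network, geneSet) {
  ed <- ppiEdges(network)
  sel <- ed$protein1 %in% geneSet & ed$protein2 %in% geneSet
  ends <- c(ed$protein1[sel], ed$protein2[sel])
  deg <- setNames(integer(length(geneSet)), geneSet)
  if (length(ends)) {
    tab <- table(ends)
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

#' Observed hub statistic on the induced subgraph
#'
#' Degrees count retained edges with both endpoints inside the gene set;
#' the hub is the maximum-degree node, ties broken lexicographically (and
#' all tied nodes reported).
#'
#' @param network a [PPINetwork] (typically after [recombineScores()]).
#' @param gene_set character vector of gene ids.
#' @return list (`HubResult`, observed part): `hub`, `max_degree`,
#'   `degrees` (named vector), `ties`.
#' @export
hubStatistic <- function(network, gene_set) {
  gene_set <- intersect(gene_set, ppiNodes(network))
  deg <- induceDegrees(network, sort(gene_set))
  if (!length(deg)) return(list(hub = NA_character_, max_degree = 0L,
                                degrees = deg, ties = character(0)))
  mx <- max(deg)
  ties <- sort(names(deg)[deg == mx])
  list(hub = ties[1], max_degree = as.integer(mx), degrees = deg,
       ties = ties)
}

#' Max-degree permutation test for the hub protein
#'
#' Draws `n_permutations` random gene sets of the observed size (without
#' replacement) from the combined associated-module gene universe, records
#' the maximum induced-subgraph degree of each, and reports the add-one
#' empirical p-value `p = (1 + #{stat_b >= observed}) / (1 + B)`.
#'
#' @param network a [PPINetwork] (after [recombineScores()]).
#' @param universe gene universe to draw from (combined associated-module
#'   genes).
#' @param set_size size of each random set.
#' @param observed observed max degree (e.g. from [hubStatistic()]).
#' @param n_permutations number of draws B.
#' @param seed RNG seed (fixed seed implies a reproducible p).
#' @return list: `p`, `observed`, `perm_stats` (length B), `n_permutations`.
#' @export
permutationTest <- function(network, universe, set_size, observed,
                            n_permutations = 10000L, seed = 1L) {
  universe <- intersect(universe, ppiNodes(network))
  if (set_size > length(universe))
    stop("set size exceeds the gene universe")
  set.seed(seed)
  # dense incidence over the universe for speed
  ed <- ppiEdges(network)
  sel <- ed$protein1 %in% universe & ed$protein2 %in% universe
  i1 <- match(ed$protein1[sel], universe)
  i2 <- match(ed$protein2[sel], universe)
  n <- length(universe)
  A <- matrix(FALSE, n, n)
  A[cbind(i1, i2)] <- TRUE
  A[cbind(i2, i1)] <- TRUE
  stats_b <- vapply(seq_len(n_permutations), function(b) {
    s <- sample.int(n, set_size)
    max(colSums(A[s, s, drop = FALSE]))
  }, numeric(1))
  p <- (1 + sum(stats_b >= observed)) / (1 + n_permutations)
  list(p = p, observed = observed, perm_stats = stats_b,
       n_permutations = n_permutations)
}
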