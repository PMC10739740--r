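#' @import methods
#' @importFrom stats cor sd var median quantile rnorm runif rpois rgamma rbinom
#'   hclust cutree dist as.dist lm.fit glm binomial p.adjust fisher.test
#'   chisq.test wilcox.test phyper pnorm coef setNames prcomp ks.test
#' @importFrom utils read.delim write.table head combn
NULL

#' ModuleSet: gene-to-module assignment with eigengenes, MM and GS
#'
#' Container for the result of co-expression module detection. Module label 0
#' means unassigned (the conventional "grey" set). Eigengenes are unit-norm
#' first right singular vectors of the per-module standardised expression
#' block, sign-oriented so each correlates positively with the module's mean
#' expression profile.
#'
#' @slot genes character vector of gene identifiers covering the network.
#' @slot labels integer vector, parallel to `genes`; 0 = unassigned.
#' @slot eigengenes numeric matrix, samples x modules; column names `ME<k>`.
#' @slot membership numeric matrix, genes x modules, Pearson correlation of
#'   each gene with each module eigengene (kME).
#' @slot significance numeric vector, per-gene Pearson correlation with the
#'   binary phenotype (GS); `NA` until computed.
#' @slot assocModules integer vector of phenotype-associated module labels
#'   (empty until association has been run).
#' @export
setClass("ModuleSet",
  representation(
    genes = "character",
    labels = "integer",
    eigengenes = "matrix",
    membership = "matrix",
    significance = "numeric",
    assocModules = "integer"
  ),
  prototype(
    eigengenes = matrix(numeric(0), 0, 0),
    membership = matrix(numeric(0), 0, 0),
    significance = numeric(0),
    assocModules = integer(0)
  )
)

setValidity("ModuleSet", function(object) {
  msg <- character(0)
  if (length(object@labels) != length(object@genes))
    msg <- c(msg, "labels and genes must have equal length")
  if (any(object@labels < 0L))
    msg <- c(msg, "labels must be >= 0 (0 = unassigned)")
  if (anyDuplicated(object@genes))
    msg <- c(msg, "gene ids must be unique")
  if (ncol(object@eigengenes) > 0) {
    nm <- colnames(object@eigengenes)
    if (is.null(nm) || anyDuplicated(nm))
      msg <- c(msg, "eigengene columns must be uniquely named")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ModuleSet compact display
#' @param object a `ModuleSet`
#' @export
setMethod("show", "ModuleSet", function(object) {
  k <- sort(unique(object@labels[object@labels > 0L]))
  cat("ModuleSet with", length(object@genes), "genes,",
      length(k), "modules\n")
  if (length(k)) {
    sz <- table(factor(object@labels[object@labels > 0L], levels = k))
    cat("  module sizes:", paste(sprintf("%d:%d", k, as.integer(sz)),
                                 collapse = " "), "\n")
  }
  cat("  unassigned:", sum(object@labels == 0L), "\n")
  if (ncol(object@eigengenes))
    cat("  eigengenes:", nrow(object@eigengenes), "samples x",
        ncol(object@eigengenes), "modules\n")
  if (length(object@assocModules))
    cat("  phenotype-associated modules:",
        paste(object@assocModules, collapse = ", "), "\n")
  invisible(NULL)
})

#' @rdname ModuleSet
#' @param genes,labels,eigengenes,membership,significance,assocModules see slots
#' @export
ModuleSet <- function(genes, labels,
                      eigengenes = matrix(numeric(0), 0, 0),
                      membership = matrix(numeric(0), 0, 0),
                      significance = numeric(0),
                      assocModules = integer(0)) {
  new("ModuleSet", genes = as.character(genes), labels = as.integer(labels),
      eigengenes = eigengenes, membership = membership,
      significance = significance, assocModules = as.integer(assocModules))
}

#' @rdname ModuleSet
#' @param x a `ModuleSet`
#' @export
moduleLabels <- function(x) setNames(x@labels, x@genes)

#' @rdname ModuleSet
#' @export
moduleEigengeneMatrix <- function(x) x@eigengenes

#' @rdname ModuleSet
#' @export
moduleGenes <- function(x, modules = NULL) {
  if (is.null(modules)) modules <- sort(unique(x@labels[x@labels > 0L]))
  x@genes[x@labels %in% modules]
}

#' @rdname ModuleSet
#' @param modules integer module labels to extract genes for
#' @export
associatedModules <- function(x) x@assocModules

#' PPINetwork: protein-protein interaction graph with per-channel scores
#'
#' Undirected simple graph whose edges carry per-evidence-channel confidence
#' scores in `[0, 1]` (experiments, database, textmining, coexpression,
#' neighbourhood, fusion, cooccurrence) plus a combined score integrating the
#' channels under a prior-corrected noisy-OR.
#'
#' @slot nodes character vector of node (gene/protein) identifiers.
#' @slot edges data.frame with columns `protein1`, `protein2`, one column per
#'   channel, and `combined`.
#' @export
setClass("PPINetwork",
  representation(nodes = "character", edges = "data.frame"))

ppiChannels <- function() {
  c("experiments", "database", "textmining", "coexpression",
    "neighbourhood", "fusion", "cooccurrence")
}

setValidity("PPINetwork", function(object) {
  msg <- character(0)
  ed <- object@edges
  need <- c("protein1", "protein2", ppiChannels(), "combined")
  if (!all(need %in% names(ed)))
    msg <- c(msg, paste("edges must have columns:", paste(need, collapse = " ")))
  else {
    if (nrow(ed)) {
      if (any(ed$protein1 == ed$protein2)) msg <- c(msg, "self-loops not allowed")
      sc <- as.matrix(ed[, c(ppiChannels(), "combined")])
      if (any(sc < 0 | sc > 1)) msg <- c(msg, "scores must lie in [0, 1]")
      if (!all(c(ed$protein1, ed$protein2) %in% object@nodes))
        msg <- c(msg, "edge endpoints must be listed in nodes")
      key <- paste(pmin(ed$protein1, ed$protein2), pmax(ed$protein1, ed$protein2))
      if (anyDuplicated(key)) msg <- c(msg, "duplicate undirected edges")
    }
  }
  if (anyDuplicated(object@nodes)) msg <- c(msg, "node ids must be unique")
  if (length(msg)) msg else TRUE
})

#' @describeIn PPINetwork compact display
#' @param object a `PPINetwork`
#' @export
setMethod("show", "PPINetwork", function(object) {
  cat("PPINetwork with", length(object@nodes), "nodes and",
      nrow(object@edges), "edges\n")
  invisible(NULL)
})

#' @rdname PPINetwork
#' @param nodes,edges see slots
#' @export
PPINetwork <- function(nodes, edges) {
  new("PPINetwork", nodes = as.character(nodes), edges = edges)
}

#' @rdname PPINetwork
#' @param x a `PPINetwork`
#' @export
ppiNodes <- function(x) x@nodes

#' @rdname PPINetwork
#' @export
ppiEdges <- function(x) x@edges
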