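#' @title Over-representation analysis
#' @name enrichment
NULL

#' Hypergeometric over-representation of module genes in gene sets
#'
#' For each set, `p = P(X >= n)` with
#' `X ~ Hypergeometric(|universe|, N, |module|)`, where `N` is the set size
#' after intersection with the universe and `n` the overlap with the module.
#' BH adjustment is applied across the sets of the collection.
#' `gene_ratio = n / |module in universe|` (the usual ORA convention).
#' Results are ordered by q, then p, then set name, so output is
#' checksum-stable.
#'
#' @param module_genes character vector of module gene ids.
#' @param sets named list of gene sets (e.g. from [readGMT()]).
#' @param universe character vector of background gene ids (convention:
#'   the post-filter network genes).
#' @return data.frame with `set`, `N`, `n`, `p`, `q`, `gene_ratio`, `genes`.
#' @export
oraFisher <- function(module_genes, sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  mod <- intersect(unique(module_genes), universe)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), universe)
    ov <- intersect(s, mod)
    N <- length(s); n <- length(ov)
    p <- phyper(n - 1L, N, length(universe) - N, length(mod),
                lower.tail = FALSE)
    data.frame(set = nm, N = N, n = n, p = p,
               gene_ratio = if (length(mod)) n / length(mod) else NA_real_,
               genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$N > 0, , drop = FALSE]
  out$q <- bhFDR(out$p)
  out <- out[order(out$q, out$p, out$set), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("set", "N", "n", "p", "q", "gene_ratio", "genes")]
}

#' @rdname oraFisher
#' @param results data.frame from [oraFisher()].
#' @param path output TSV path.
#' @export
writeEnrichment <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
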