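#' @title SNP-to-gene annotation with LD-proxy expansion
#' @description Lead GWAS SNPs are expanded with their LD proxies
#'   (r-squared at or above the threshold), then annotated to protein-coding
#'   genes by three rules: (1) the SNP falls inside the gene body (0-based
#'   half-open); (2) the nearest gene ending before the SNP and the nearest
#'   gene starting after it (both flanks reported, distance measured from
#'   gene-body boundaries, strand ignored); (3) the SNP falls inside a
#'   chromatin-interaction other-end whose bait is the gene promoter.
#' @name gwas_annotation
NULL

#' Expand lead SNPs with LD proxies
#'
#' @param leads character vector of lead SNP ids.
#' @param ld either a signed SNP x SNP correlation matrix (dimnames
#'   required; values are squared internally) or a proxy data.frame with
#'   columns `lead`, `proxy`, `r2`.
#' @param r2_threshold minimum r-squared (default 0.7).
#' @return character vector: union of leads and their proxies.
#' @export
expandProxies <- function(leads, ld, r2_threshold = 0.7) {
  if (is.matrix(ld)) {
    present <- intersect(leads, rownames(ld))
    prox <- character(0)
    for (s in present) {
      r2 <- ld[s, ]^2
      prox <- c(prox, colnames(ld)[r2 >= r2_threshold])
    }
    sort(unique(c(leads, prox)))
  } else {
    if (!all(c("lead", "proxy", "r2") %in% names(ld)))
      stop("proxy table needs columns lead, proxy, r2")
    sel <- ld$lead %in% leads & ld$r2 >= r2_threshold
    sort(unique(c(leads, ld$proxy[sel])))
  }
}

#' Annotate SNP positions to genes by the three rules
#'
#' @param snps data.frame with `snp`, `chr`, `pos` (1-based SNP positions).
#' @param genes [GenomicRanges::GRanges] gene models named by gene id
#'   (1-based inclusive in R, as produced by [readBed()]).
#' @param interactions optional BEDPE data.frame ([readBedpe()]): bait
#'   (promoter) interval first with its gene id in `name`, other-end second;
#'   coordinates 0-based half-open.
#' @return data.frame with `snp`, `gene`, `rule` (`body`,
#'   `nearest_preceding`, `nearest_following`, `interaction`); a SNP on a
#'   chromosome absent from the models yields no rows (warning).
#' @export
annotateSnps <- function(snps, genes, interactions = NULL) {
  stopifnot(all(c("snp", "chr", "pos") %in% names(snps)))
  out <- list()
  gchr <- as.character(GenomicRanges::seqnames(genes))
  gstart <- GenomicRanges::start(genes)
  gend <- GenomicRanges::end(genes)
  gid <- names(genes)
  for (i in seq_len(nrow(snps))) {
    sid <- snps$snp[i]; chr <- as.character(snps$chr[i]); pos <- snps$pos[i]
    onchr <- gchr == chr
    if (!any(onchr)) {
      warning("SNP ", sid, " on chromosome ", chr, " absent from gene models")
      next
    }
    # rule 1: gene body containment
    inbody <- onchr & gstart <= pos & pos <= gend
    for (g in gid[inbody])
      out[[length(out) + 1L]] <- data.frame(snp = sid, gene = g,
                                            rule = "body")
    # rule 2: nearest flanking genes by body boundary
    prec <- onchr & gend < pos
    if (any(prec)) {
      g <- gid[prec][which.max(gend[prec])]
      out[[length(out) + 1L]] <- data.frame(snp = sid, gene = g,
                                            rule = "nearest_preceding")
    }
    foll <- onchr & gstart > pos
    if (any(foll)) {
      g <- gid[foll][which.min(gstart[foll])]
      out[[length(out) + 1L]] <- data.frame(snp = sid, gene = g,
                                            rule = "nearest_following")
    }
    # rule 3: promoter-interaction other-end containment
    if (!is.null(interactions) && nrow(interactions)) {
      hit <- interactions$chrom2 == chr &
        interactions$start2 < pos & pos <= interactions$end2
      for (g in unique(interactions$name[hit]))
        out[[length(out) + 1L]] <- data.frame(snp = sid, gene = g,
                                              rule = "interaction")
    }
  }
  if (!length(out))
    return(data.frame(snp = character(0), gene = character(0),
                      rule = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- unique(res)
  rownames(res) <- NULL
  res
}

#' Restrict annotations to module genes
#'
#' @param annotations data.frame from [annotateSnps()].
#' @param mset a [ModuleSet] or character vector of gene ids.
#' @param modules optional module labels to restrict to (default: the
#'   phenotype-associated modules if recorded, else all).
#' @return the filtered annotation data.frame (rule tags preserved).
#' @export
filterToModules <- function(annotations, mset, modules = NULL) {
  if (is(mset, "ModuleSet")) {
    if (is.null(modules))
      modules <- if (length(associatedModules(mset))) associatedModules(mset)
                 else sort(unique(mset@labels[mset@labels > 0L]))
    keep <- moduleGenes(mset, modules)
  } else keep <- as.character(mset)
  out <- annotations[annotations$gene %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
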