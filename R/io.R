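#' @title Readers and writers for the pipeline's plain-text formats
#' @description Counts and sample tables are tab-delimited; summary statistics
#'   use the header `snp chr pos a1 a2 beta se maf n`; gene models are BED
#'   (0-based half-open); promoter interactions are BEDPE; gene sets are GMT;
#'   the PPI table carries one column per evidence channel. All writers
#'   produce files that round-trip bit-identically through their readers.
#' @name io
NULL

#' Build a SummarizedExperiment from a count matrix and sample table
#'
#' @param values gene x sample numeric matrix.
#' @param samples data.frame with one row per column of `values`; must
#'   contain `sample_id` matching the column names.
#' @param layer one of `raw`, `normalised`, `transformed`, `residualised`;
#'   stored in `metadata(se)$layer`. The raw layer must be integer-valued and
#'   non-negative.
#' @return a [SummarizedExperiment::SummarizedExperiment].
#' @export
makeExpressionExperiment <- function(values, samples = NULL, layer = "raw") {
  layer <- match.arg(layer, c("raw", "normalised", "transformed",
                              "residualised"))
  if (anyNA(values)) stop("expression values must not contain NA")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("gene ids must be present and unique")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("sample ids must be present and unique")
  if (layer == "raw" &&
      (any(values < 0) || any(values != round(values))))
    stop("raw layer must contain non-negative integer counts")
  if (is.null(samples))
    samples <- data.frame(sample_id = colnames(values),
                          stringsAsFactors = FALSE)
  if (!identical(as.character(samples$sample_id), colnames(values)))
    stop("samples$sample_id must match the count matrix columns")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = setNames(list(values), layer),
    colData = S4Vectors::DataFrame(samples, row.names = samples$sample_id))
  S4Vectors::metadata(se)$layer <- layer
  se
}

exprLayer <- function(se) {
  ly <- S4Vectors::metadata(se)$layer
  if (is.null(ly)) SummarizedExperiment::assayNames(se)[1] else ly
}

exprValues <- function(se) {
  if (is(se, "SummarizedExperiment"))
    SummarizedExperiment::assay(se, 1L) else as.matrix(se)
}

setLayer <- function(se, values, layer) {
  out <- makeExpressionExperiment(
    values, as.data.frame(SummarizedExperiment::colData(se)), layer = layer)
  out
}

#' @rdname io
#' @param x matrix to write (genes as rows, header of sample ids).
#' @param path file path.
#' @export
writeCounts <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
readCounts <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname io
#' @param samples data.frame sample table.
#' @export
writeSampleTable <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
readSampleTable <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

sumstatColumns <- function() c("snp", "chr", "pos", "a1", "a2",
                               "beta", "se", "maf", "n")

#' Validate a summary-statistics data.frame
#'
#' Requires columns `snp chr pos a1 a2 beta se maf n`, positive standard
#' errors, minor allele frequencies in (0, 0.5], and a single chromosome.
#'
#' @param stats data.frame of per-SNP summary statistics.
#' @return the validated data.frame, invisibly.
#' @export
validateSummaryStats <- function(stats) {
  miss <- setdiff(sumstatColumns(), names(stats))
  if (length(miss))
    stop("summary statistics missing column(s): ", paste(miss, collapse = ", "))
  if (any(stats$se <= 0)) stop("se must be > 0")
  if (any(stats$maf <= 0 | stats$maf > 0.5))
    stop("maf must lie in (0, 0.5]")
  if (length(unique(stats$chr)) > 1L)
    stop("a summary-statistics region must lie on one chromosome")
  if (anyDuplicated(stats$snp)) stop("duplicate SNP ids")
  invisible(stats)
}

#' @rdname io
#' @param stats summary-statistics data.frame (`snp chr pos a1 a2 beta se maf n`).
#' @export
writeSummaryStats <- function(stats, path) {
  validateSummaryStats(stats)
  write.table(stats[, sumstatColumns()], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @param trait_type `"cc"` (case-control) or `"quant"`; attached as an
#'   attribute used to pick the ABF prior effect SD.
#' @export
readSummaryStats <- function(path, trait_type = c("quant", "cc")) {
  trait_type <- match.arg(trait_type)
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(chr = "character"))
  validateSummaryStats(df)
  attr(df, "trait_type") <- trait_type
  df
}

#' @rdname io
#' @param ld signed SNP x SNP correlation matrix with dimnames.
#' @export
writeLDMatrix <- function(ld, path) {
  df <- data.frame(snp = rownames(ld), ld, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
readLDMatrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname io
#' @param gr a [GenomicRanges::GRanges] of gene models with `name` metadata.
#' @export
writeBed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read gene models from BED (0-based half-open on disk)
#'
#' @param path BED file; the `name` column carries the gene id.
#' @param one_based set `TRUE` if the file uses 1-based inclusive starts
#'   (they are shifted back to BED convention on read).
#' @return [GenomicRanges::GRanges] named by gene id.
#' @export
readBed <- function(path, one_based = FALSE) {
  gr <- rtracklayer::import(path, format = "BED")
  if (one_based) GenomicRanges::start(gr) <- GenomicRanges::start(gr) - 1L
  names(gr) <- gr$name
  gr
}

bedpeColumns <- function() c("chrom1", "start1", "end1", "chrom2", "start2",
                             "end2", "name")

#' @rdname io
#' @param bedpe data.frame with columns
#'   `chrom1 start1 end1 chrom2 start2 end2 name` (bait first, gene id in
#'   `name`; coordinates 0-based half-open).
#' @export
writeBedpe <- function(bedpe, path) {
  miss <- setdiff(bedpeColumns(), names(bedpe))
  if (length(miss)) stop("BEDPE missing column(s): ",
                         paste(miss, collapse = ", "))
  write.table(bedpe[, bedpeColumns()], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
readBedpe <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   colClasses = c(V1 = "character", V4 = "character"))
  names(df) <- bedpeColumns()[seq_len(ncol(df))]
  df
}

#' @rdname io
#' @param network a [PPINetwork].
#' @export
writePPITable <- function(network, path) {
  write.table(ppiEdges(network), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @param nodes optional full node universe (isolated nodes are not
#'   recoverable from an edge list alone).
#' @export
readPPITable <- function(path, nodes = NULL) {
  ed <- read.delim(path, stringsAsFactors = FALSE)
  for (col in c(ppiChannels(), "combined"))
    if (col %in% names(ed)) ed[[col]] <- as.numeric(ed[[col]])
  if (is.null(nodes)) nodes <- sort(unique(c(ed$protein1, ed$protein2)))
  PPINetwork(nodes, ed)
}

#' @rdname io
#' @param sets named list of character vectors of gene ids.
#' @export
writeGMT <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", unique(sets[[nm]])), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Thin wrapper over [fgsea::gmtPathways()]; duplicate genes within a set are
#' removed.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
readGMT <- function(path) {
  sets <- fgsea::gmtPathways(path)
  lapply(sets, unique)
}
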