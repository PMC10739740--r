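#' @title End-to-end pipeline orchestration
#' @description Runs simulate (optional) -> preprocess -> deconvolve ->
#'   network -> associate -> enrich -> coloc + annotate -> hub from one
#'   configuration, writing every stage output as tab-delimited text plus a
#'   JSON manifest with the seed and an MD5 checksum per output, so a rerun
#'   with the same configuration is byte-identical.
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param sim a [simConfig()]; used to generate the fixture bundle when
#'   `input_dir` is `NULL`, and as the source of the global seed.
#' @param input_dir directory containing an existing fixture bundle (the
#'   file names of [writeFixtureBundle()]); `NULL` simulates one.
#' @param qc list: `min_count`, `min_samples`, `top_expressed`,
#'   `height_factor`, `variable_gene_quantile`.
#' @param network a [networkParams()] list.
#' @param association list: `fdr_level`, `covariates`.
#' @param priors a [colocPriors()] list.
#' @param annotation list: `ld_r2_threshold`, `lead_z` (|z| above which a
#'   GWAS SNP is a lead).
#' @param top_genes a [topGeneConfig()] list.
#' @param coloc_min_snps minimum SNPs per colocalisation region.
#' @return configuration list.
#' @export
pipelineConfig <- function(sim = simConfig(),
                           input_dir = NULL,
                           qc = list(min_count = 5L, min_samples = 10L,
                                     top_expressed = 100L, height_factor = 3,
                                     variable_gene_quantile = 0.75),
                           network = networkParams(),
                           association = list(fdr_level = 0.20,
                                              covariates = character(0)),
                           priors = colocPriors(),
                           annotation = list(ld_r2_threshold = 0.7,
                                             lead_z = 5.45),
                           top_genes = topGeneConfig(),
                           coloc_min_snps = 50L) {
  list(sim = sim, input_dir = input_dir, qc = qc, network = network,
       association = association, priors = priors, annotation = annotation,
       top_genes = top_genes, coloc_min_snps = coloc_min_snps)
}

#' Run the full pipeline
#'
#' @param config a [pipelineConfig()] list.
#' @param out_dir output directory for stage results and the manifest.
#' @return the manifest list, invisibly (also written as
#'   `manifest.json`).
#' @export
runPipeline <- function(config, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- config$sim$seed
  manifest <- list(seed = seed, stages = list())
  written <- character(0)

  # ---- inputs -------------------------------------------------------------
  if (is.null(config$input_dir)) {
    input_dir <- file.path(out_dir, "inputs")
    paths <- writeFixtureBundle(input_dir, config$sim)
  } else {
    input_dir <- config$input_dir
    paths <- setNames(file.path(input_dir,
      c("counts.tsv", "samples.tsv", "gwas.tsv", "eqtl.tsv", "ld.tsv",
        "genes.bed", "interactions.bedpe", "ppi.tsv", "sets.gmt",
        "reference_counts.tsv", "reference_labels.tsv", "truth.json")),
      c("counts", "samples", "gwas", "eqtl", "ld", "genes", "interactions",
        "ppi", "gmt", "reference_counts", "reference_labels", "truth"))
  }
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  manifest$stages$inputs <- list(dir = input_dir,
                                 files = as.list(tools::md5sum(paths)))

  counts <- readCounts(paths[["counts"]])
  samples <- readSampleTable(paths[["samples"]])
  se <- makeExpressionExperiment(counts, samples, layer = "raw")

  # ---- deconvolution ------------------------------------------------------
  ref <- readCounts(paths[["reference_counts"]])
  reflab <- readSampleTable(paths[["reference_labels"]])
  sig <- buildSignature(ref, reflab$cell_type, bulk_genes = rownames(counts))
  props <- estimateProportions(counts, sig)
  propCovs <- selectProportionCovariates(props)
  # if every kept column is retained the proportions sum to one and are
  # collinear with the intercept; drop the least abundant kept type
  if (length(propCovs) &&
      all(abs(rowSums(props[propCovs]) - 1) < 1e-6)) {
    mu <- vapply(props[propCovs], mean, numeric(1))
    propCovs <- setdiff(propCovs, names(which.min(mu)))
  }
  samples2 <- appendProportions(samples, props, keep = propCovs)
  propPath <- file.path(out_dir, "proportions.tsv")
  writeSampleTable(props, propPath)
  written <- c(written, propPath)
  manifest$stages$deconvolve <- list(celltypes_kept = propCovs)

  # ---- preprocess ---------------------------------------------------------
  qc <- config$qc
  se <- filterGenes(se, qc$min_count, qc$min_samples)
  tr <- normaliseTransform(se)
  outliers <- detectOutlierSamples(tr, qc$top_expressed, qc$height_factor)
  tr <- selectVariableGenes(tr, qc$variable_gene_quantile)
  covs <- c("sex", "batch", "pcr_cycles", propCovs)
  cd <- as.data.frame(SummarizedExperiment::colData(tr))
  cd[setdiff(propCovs, names(cd))] <-
    samples2[match(cd$sample_id, samples2$sample_id),
             setdiff(propCovs, names(cd)), drop = FALSE]
  tr2 <- makeExpressionExperiment(exprValues(tr), cd, layer = "transformed")
  res <- residualise(tr2, covs)
  manifest$stages$preprocess <- list(
    genes_after_filter = nrow(se),
    genes_in_network = nrow(res),
    outlier_samples = as.list(outliers))

  # ---- network ------------------------------------------------------------
  mset <- buildNetwork(res, phenotype = samples$phenotype, config$network)
  modPath <- file.path(out_dir, "modules.tsv")
  labs <- moduleLabels(mset)
  ownMM <- rep(NA_real_, length(labs))
  has <- labs > 0L & sprintf("ME%d", labs) %in% colnames(mset@membership)
  ownMM[has] <- mset@membership[cbind(which(has),
    match(sprintf("ME%d", labs[has]), colnames(mset@membership)))]
  write.table(data.frame(gene = names(labs), label = labs, mm_own = ownMM,
                         gs = mset@significance[names(labs)]),
              modPath, sep = "\t", quote = FALSE, row.names = FALSE)
  mePath <- file.path(out_dir, "eigengenes.tsv")
  write.table(data.frame(sample_id = rownames(mset@eigengenes),
                         mset@eigengenes, check.names = FALSE),
              mePath, sep = "\t", quote = FALSE, row.names = FALSE)
  written <- c(written, modPath, mePath)
  manifest$stages$network <- list(
    n_modules = ncol(mset@eigengenes),
    beta = config$network$beta)

  # ---- association --------------------------------------------------------
  assoc <- associateModules(mset@eigengenes, samples,
                            covariates = config$association$covariates,
                            fdr_level = config$association$fdr_level)
  assocPath <- file.path(out_dir, "association.tsv")
  write.table(assoc, assocPath, sep = "\t", quote = FALSE, row.names = FALSE)
  written <- c(written, assocPath)
  sigMods <- as.integer(sub("^ME", "", assoc$module[assoc$significant]))
  fallback <- FALSE
  if (!length(sigMods) && nrow(assoc)) {
    sigMods <- as.integer(sub("^ME", "",
      assoc$module[which.min(assoc$q)]))
    fallback <- TRUE
  }
  mset@assocModules <- sigMods
  manifest$stages$associate <- list(significant_modules = sigMods,
                                    fallback_top_module = fallback)

  # ---- enrichment ---------------------------------------------------------
  sets <- readGMT(paths[["gmt"]])
  universe <- mset@genes
  enr <- if (length(sigMods)) do.call(rbind, lapply(sigMods, function(m) {
    r <- oraFisher(moduleGenes(mset, m), sets, universe)
    cbind(module = sprintf("ME%d", m), r)
  })) else data.frame(module = character(0), set = character(0))
  enrPath <- file.path(out_dir, "enrichment.tsv")
  writeEnrichment(enr, enrPath)
  written <- c(written, enrPath)
  manifest$stages$enrich <- list(n_tests = nrow(enr))

  # ---- colocalisation + annotation ---------------------------------------
  gwas <- readSummaryStats(paths[["gwas"]], trait_type = "cc")
  eqtl <- readSummaryStats(paths[["eqtl"]], trait_type = "quant")
  harm <- harmoniseSumstats(gwas, eqtl, min_snps = config$coloc_min_snps)
  genes <- readBed(paths[["genes"]])
  assocGenes <- moduleGenes(mset, sigMods)
  pp4 <- setNames(numeric(0), character(0))
  colocRows <- list()
  if (!is.null(harm)) {
    regions <- buildRegions(genes[intersect(assocGenes, names(genes))],
                            harm$gwas)
    for (gid in names(regions)) {
      idx <- match(regions[[gid]]$snps, harm$gwas$snp)
      idx <- idx[!is.na(idx)]
      if (length(idx) < config$coloc_min_snps) next
      sub <- list(gwas = harm$gwas[idx, ], eqtl = harm$eqtl[idx, ])
      attr(sub$gwas, "trait_type") <- "cc"
      attr(sub$eqtl, "trait_type") <- "quant"
      cr <- colocABF(sub, config$priors)
      pp4[gid] <- unname(cr$pp["PP4"])
      colocRows[[gid]] <- data.frame(gene = gid, n_snps = cr$n_snps,
                                     t(cr$pp), evidence = cr$evidence)
    }
  }
  colocPath <- file.path(out_dir, "coloc.tsv")
  colocDf <- if (length(colocRows)) do.call(rbind, colocRows) else
    data.frame(gene = character(0))
  write.table(colocDf, colocPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  written <- c(written, colocPath)

  leadSel <- abs(gwas$beta / gwas$se) >= config$annotation$lead_z
  leads <- gwas$snp[leadSel]
  ld <- readLDMatrix(paths[["ld"]])
  snpSet <- expandProxies(leads, ld, config$annotation$ld_r2_threshold)
  ann <- annotateSnps(gwas[gwas$snp %in% snpSet, c("snp", "chr", "pos")],
                      genes, readBedpe(paths[["interactions"]]))
  annMod <- filterToModules(ann, mset, sigMods)
  annPath <- file.path(out_dir, "annotation.tsv")
  write.table(annMod, annPath, sep = "\t", quote = FALSE, row.names = FALSE)
  written <- c(written, annPath)
  manifest$stages$coloc <- list(n_regions = length(colocRows),
                                n_evidence = sum(pp4 >= 0.5),
                                n_leads = length(leads),
                                n_annotated = nrow(annMod))

  # ---- hub ----------------------------------------------------------------
  ppi <- readPPITable(paths[["ppi"]])
  top <- if (length(sigMods)) buildTopGeneSet(pp4, mset, config$top_genes)
         else data.frame(gene = character(0))
  net <- recombineScores(ppi, config$top_genes$channel_exclusions,
                         config$top_genes$prior,
                         config$top_genes$combined_score_min)
  hubRes <- list(hub = NA_character_, max_degree = 0L)
  permP <- NA_real_
  if (nrow(top)) {
    hubRes <- hubStatistic(net, top$gene)
    uni <- intersect(assocGenes, ppiNodes(net))
    ssize <- length(intersect(top$gene, ppiNodes(net)))
    if (ssize >= 1L && ssize <= length(uni)) {
      pt <- permutationTest(net, uni, ssize, hubRes$max_degree,
                            config$top_genes$n_permutations,
                            seed = seed + 7L)
      permP <- pt$p
    }
  }
  hubPath <- file.path(out_dir, "hub.json")
  jsonlite::write_json(list(hub = hubRes$hub,
                            max_degree = hubRes$max_degree,
                            set_size = nrow(top),
                            permutation_p = permP),
                       hubPath, auto_unbox = TRUE, digits = NA)
  written <- c(written, hubPath)
  manifest$stages$hub <- list(hub = hubRes$hub,
                              max_degree = hubRes$max_degree,
                              permutation_p = permP)

  manifest$outputs <- as.list(tools::md5sum(written))
  names(manifest$outputs) <- basename(written)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
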