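#' @title Synthetic-data generators with known ground truth
#' @description Every pipeline input can be generated with the statistical
#'   structure the analysis assumes, so all downstream stages are testable
#'   without external data. Each generator seeds the global RNG once from the
#'   configuration seed (plus a fixed per-generator offset, so the datasets
#'   are independent sub-streams of one master seed).
#' @name simulate
NULL

geneIds <- function(n) sprintf("G%05d", seq_len(n))
sampleIds <- function(n) sprintf("S%03d", seq_len(n))
snpIds <- function(n) sprintf("rs%04d", seq_len(n))

rdirichlet <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Simulate a bulk count matrix with planted co-expression modules
#'
#' Counts are Poisson-lognormal: a latent log-expression per gene and sample
#' is `loading * module_factor + covariate effects + gene baseline`, and the
#' observed count is Poisson around `exp(latent)` scaled to the sample's
#' library size. Module factors of the first `n_assoc_modules` modules are
#' shifted by `factor_effect` standard deviations in cases; background genes
#' are independent noise.
#'
#' @param config a [simConfig()] object.
#' @return list with `counts` (a [SummarizedExperiment::SummarizedExperiment]
#'   of raw counts with the sample table as `colData`), `samples`
#'   (data.frame), and `truth` (module labels, associated module ids, true
#'   cell proportions, per-sample library sizes).
#' @export
simulateExpression <- function(config) {
  validateSimConfig(config)
  set.seed(config$seed)
  nS <- config$n_cases + config$n_controls
  G <- config$n_genes
  sid <- sampleIds(nS)
  gid <- geneIds(G)
  phenotype <- c(rep(1L, config$n_cases), rep(0L, config$n_controls))
  sex <- rbinom(nS, 1L, 0.5)
  batch <- sample(rep_len(1:4, nS))
  pcr_cycles <- sample(15:18, nS, replace = TRUE)
  alpha <- rep_len(config$dirichlet_alpha, config$n_celltypes)
  props <- rdirichlet(nS, alpha)
  colnames(props) <- sprintf("CT%d", seq_len(config$n_celltypes))
  libsize <- exp(rnorm(nS, config$library_size_lognorm[1],
                       config$library_size_lognorm[2]))

  labels <- integer(G)
  if (length(config$module_sizes))
    labels[seq_len(sum(config$module_sizes))] <-
      rep(seq_along(config$module_sizes), config$module_sizes)

  # latent gene-sample matrix with unit variance per gene
  lam <- config$within_module_cor
  z <- matrix(rnorm(G * nS), G, nS)
  nmod <- length(config$module_sizes)
  factors <- matrix(rnorm(nmod * nS), nmod, nS)
  if (config$n_assoc_modules > 0L && nmod > 0L) {
    sh <- seq_len(config$n_assoc_modules)
    factors[sh, ] <- factors[sh, , drop = FALSE] +
      config$factor_effect * matrix(phenotype, length(sh), nS, byrow = TRUE)
  }
  for (m in seq_len(nmod)) {
    idx <- which(labels == m)
    z[idx, ] <- lam * matrix(factors[m, ], length(idx), nS, byrow = TRUE) +
      sqrt(1 - lam^2) * z[idx, , drop = FALSE]
  }

  # covariate design (centred) and per-gene random coefficients
  eff <- config$covariate_effects
  X <- cbind(
    sex = sex - mean(sex),
    pcr = as.numeric(scale(pcr_cycles)),
    stats::model.matrix(~ 0 + factor(batch, levels = 1:4)),
    sweep(props, 2, colMeans(props))
  )
  X[is.nan(X)] <- 0
  sds <- c(eff[["sex"]], eff[["pcr"]], rep(eff[["batch"]], 4L),
           rep(eff[["celltype"]], config$n_celltypes))
  B <- matrix(rnorm(G * ncol(X)), G, ncol(X)) *
    matrix(sds, G, ncol(X), byrow = TRUE)
  covterm <- B %*% t(X)

  sigma <- 0.5                       # biological log-scale SD
  baseline <- rnorm(G, 0, 1)         # relative log abundance
  w <- exp(baseline + sigma^2 / 2)   # expected relative mean per gene
  eta <- baseline + sigma * z + covterm
  offset <- log(libsize) - log(sum(w))
  mu <- exp(sweep(eta, 2, offset, "+"))
  counts <- matrix(rpois(G * nS, as.vector(mu)), G, nS,
                   dimnames = list(gid, sid))

  samples <- data.frame(sample_id = sid, phenotype = phenotype, sex = sex,
                        batch = batch, pcr_cycles = pcr_cycles,
                        stringsAsFactors = FALSE)
  se <- makeExpressionExperiment(counts, samples, layer = "raw")
  truth <- list(
    module_label_per_gene = setNames(labels, gid),
    assoc_module_ids = seq_len(config$n_assoc_modules),
    true_proportions = data.frame(sample_id = sid, props,
                                  stringsAsFactors = FALSE),
    library_sizes = setNames(libsize, sid)
  )
  list(counts = se, samples = samples, truth = truth)
}

#' Simulate paired GWAS and eQTL summary statistics over one LD region
#'
#' Genotype correlation follows AR(1) decay `R[i, j] = ld_decay^|i-j|`.
#' Marginal z-scores are `R %*% z_causal` plus correlated noise `MVN(0, R)`,
#' and effect estimates are `z * se` with the standard approximation
#' `se = 1/sqrt(2 N maf (1-maf))`. `shared = TRUE` places the same causal SNP
#' in both traits; `FALSE` separates the two causal SNPs by at least 10 SNPs.
#' A configurable fraction of eQTL rows has its alleles swapped (with the
#' sign of beta flipped consistently) to exercise harmonisation.
#'
#' @param config a [simConfig()] object.
#' @param shared logical; one shared causal SNP vs two distinct ones.
#' @param flip_fraction fraction of eQTL SNPs emitted on the opposite allele.
#' @param palindromic_fraction fraction of SNPs given strand-ambiguous
#'   (A/T or C/G) allele pairs.
#' @return list with `gwas` and `eqtl` summary-statistic data.frames (columns
#'   `snp chr pos a1 a2 beta se maf n`), the signed LD matrix `ld`, and
#'   `truth` (causal indices and the shared flag).
#' @export
simulateSummaryStats <- function(config, shared = TRUE,
                                 flip_fraction = 0.1,
                                 palindromic_fraction = 0) {
  validateSimConfig(config)
  if (config$region_n_snps < 2L) stop("region_n_snps must be >= 2")
  set.seed(config$seed + 1000L)
  p <- config$region_n_snps
  pos <- 1e6L + seq_len(p) * 1000L
  maf <- runif(p, 0.05, 0.5)
  n <- config$sumstat_n
  sef <- 1 / sqrt(2 * n * maf * (1 - maf))
  R <- config$ld_decay^abs(outer(seq_len(p), seq_len(p), "-"))
  cR <- chol(R + diag(1e-10, p))

  ci_g <- max(1L, p %/% 2L)
  ci_e <- if (shared) ci_g else min(p, ci_g + max(10L, p %/% 10L))

  margZ <- function(ci, beta_causal) {
    zc <- beta_causal / sef[ci]
    R[, ci] * zc + as.vector(t(cR) %*% rnorm(p))
  }
  z_g <- margZ(ci_g, config$gwas_beta)
  z_e <- margZ(ci_e, config$eqtl_beta)

  pal <- list(c("A", "T"), c("C", "G"))
  nonpal <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
  isPal <- runif(p) < palindromic_fraction
  al <- t(vapply(seq_len(p), function(i) {
    pool <- if (isPal[i]) pal else nonpal
    pr <- pool[[sample.int(length(pool), 1)]]
    if (runif(1) < 0.5) rev(pr) else pr
  }, character(2)))

  mk <- function(z) data.frame(
    snp = snpIds(p), chr = "1", pos = pos, a1 = al[, 1], a2 = al[, 2],
    beta = z * sef, se = sef, maf = maf, n = n, stringsAsFactors = FALSE)
  gwas <- mk(z_g)
  eqtl <- mk(z_e)
  nflip <- round(flip_fraction * p)
  if (nflip > 0) {
    fi <- sample.int(p, nflip)
    tmp <- eqtl$a1[fi]
    eqtl$a1[fi] <- eqtl$a2[fi]
    eqtl$a2[fi] <- tmp
    eqtl$beta[fi] <- -eqtl$beta[fi]
  }
  attr(gwas, "trait_type") <- "cc"
  attr(eqtl, "trait_type") <- "quant"
  dimnames(R) <- list(gwas$snp, gwas$snp)
  list(gwas = gwas, eqtl = eqtl, ld = R,
       truth = list(causal_gwas = gwas$snp[ci_g], causal_eqtl = eqtl$snp[ci_e],
                    shared = shared))
}

#' Simulate a PPI network with per-channel scores and an optional planted hub
#'
#' Erdos-Renyi edges at `ppi_edge_prob`; each edge activates a random subset
#' of evidence channels with scores in (0.4, 0.95). The planted hub receives
#' `hub_extra_degree` additional edges towards genes of the associated
#' modules, carried by the "experiments" channel so they survive the
#' co-expression/neighbourhood/fusion exclusions used downstream.
#'
#' @param config a [simConfig()] object.
#' @param node_ids node identifiers; length must equal `n_ppi_nodes`.
#' @param assoc_genes identifiers towards which hub edges are planted
#'   (default: the first half of `node_ids`).
#' @param hub_node identifier of the planted hub (default: first of
#'   `assoc_genes`).
#' @return list with `network` (a [PPINetwork]) and `truth` (planted hub id).
#' @export
simulatePPI <- function(config, node_ids, assoc_genes = NULL,
                        hub_node = NULL) {
  validateSimConfig(config)
  if (length(node_ids) != config$n_ppi_nodes)
    stop("node_ids must have length n_ppi_nodes")
  set.seed(config$seed + 2000L)
  n <- length(node_ids)
  if (is.null(assoc_genes))
    assoc_genes <- node_ids[seq_len(max(1L, n %/% 2L))]
  assoc_genes <- intersect(assoc_genes, node_ids)
  if (is.null(hub_node)) hub_node <- assoc_genes[1L]

  ii <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  jj <- sequence((n - 1L):1L) + ii
  keep <- runif(length(ii)) < config$ppi_edge_prob
  e1 <- ii[keep]; e2 <- jj[keep]

  hub_idx <- match(hub_node, node_ids)
  if (config$hub_extra_degree > 0L) {
    targ <- setdiff(match(assoc_genes, node_ids), hub_idx)
    have <- c(e2[e1 == hub_idx], e1[e2 == hub_idx])
    targ <- setdiff(targ, have)
    if (length(targ) < config$hub_extra_degree)
      stop("not enough associated-module nodes to plant the hub degree")
    targ <- sample(targ, config$hub_extra_degree)
    e1 <- c(e1, pmin(hub_idx, targ)); e2 <- c(e2, pmax(hub_idx, targ))
    planted <- c(rep(FALSE, sum(keep)), rep(TRUE, length(targ)))
  } else planted <- rep(FALSE, sum(keep))

  m <- length(e1)
  ch <- ppiChannels()
  sc <- matrix(0, m, length(ch), dimnames = list(NULL, ch))
  if (m > 0) {
    act <- matrix(runif(m * length(ch)) < 0.35, m, length(ch))
    none <- !rowSums(act)
    act[cbind(which(none), sample.int(length(ch), sum(none), replace = TRUE))] <- TRUE
    sc[act] <- runif(sum(act), 0.4, 0.95)
    sc[planted, ] <- 0
    sc[planted, "experiments"] <- runif(sum(planted), 0.7, 0.95)
  }
  combined <- combineChannelScores(sc)
  edges <- data.frame(protein1 = node_ids[e1], protein2 = node_ids[e2],
                      sc, combined = combined, stringsAsFactors = FALSE)
  # de-duplicate edges that coincide (keep first)
  key <- paste(edges$protein1, edges$protein2)
  edges <- edges[!duplicated(key), , drop = FALSE]
  rownames(edges) <- NULL
  list(network = PPINetwork(node_ids, edges),
       truth = list(planted_hub_node = hub_node))
}

#' Simulate a labelled single-cell reference
#'
#' Per-cell-type mean profiles share a lognormal baseline with distinct
#' marker blocks elevated `marker_fold`-fold; cells are Poisson draws around
#' the type profile.
#'
#' @param config a [simConfig()] object.
#' @param n_cells_per_type cells per type.
#' @param n_marker_genes marker-block size per type.
#' @param marker_fold fold elevation of a type's marker block.
#' @param cell_depth expected counts per cell.
#' @return list with `counts` (gene x cell matrix), `labels` (cell type per
#'   cell), and `truth` (true CPM-scale mean profile per type).
#' @export
simulateSingleCellReference <- function(config, n_cells_per_type = 50L,
                                        n_marker_genes = 50L,
                                        marker_fold = 5,
                                        cell_depth = 5000) {
  validateSimConfig(config)
  set.seed(config$seed + 3000L)
  G <- config$n_genes
  K <- config$n_celltypes
  if (K * n_marker_genes > G)
    stop("marker blocks exceed the number of genes")
  gid <- geneIds(G)
  base <- exp(rnorm(G, 0, 1))
  prof <- matrix(base, G, K, dimnames = list(gid, sprintf("CT%d", seq_len(K))))
  # marker blocks occupy the trailing genes so they never overlap the
  # planted co-expression modules (which sit at the head of the gene list);
  # otherwise estimated proportions would track the module factors and
  # residualisation would erase the planted structure
  off <- G - K * n_marker_genes
  for (k in seq_len(K)) {
    idx <- off + ((k - 1L) * n_marker_genes + 1L):(k * n_marker_genes)
    prof[idx, k] <- prof[idx, k] * marker_fold
  }
  prof_cpm <- sweep(prof, 2, colSums(prof), "/") * 1e6
  ncell <- K * n_cells_per_type
  labels <- rep(colnames(prof), each = n_cells_per_type)
  counts <- matrix(0L, G, ncell,
                   dimnames = list(gid, sprintf("C%04d", seq_len(ncell))))
  for (j in seq_len(ncell)) {
    pr <- prof[, labels[j]] / sum(prof[, labels[j]])
    counts[, j] <- rpois(G, cell_depth * pr)
  }
  list(counts = counts, labels = labels, truth = list(type_means_cpm = prof_cpm))
}

#' Simulate bulk mixtures of a signature matrix with known proportions
#'
#' @param signature gene x cell-type matrix (e.g. from [buildSignature()]).
#' @param n_samples number of mixtures.
#' @param alpha Dirichlet concentration for the true proportions.
#' @param noise_sd SD of multiplicative lognormal noise per gene and sample.
#' @param seed RNG seed.
#' @return list with `bulk` (gene x sample matrix) and `proportions`
#'   (sample x cell-type matrix of truth).
#' @export
simulateBulkMixtures <- function(signature, n_samples = 20L,
                                 alpha = c(8, 5, 3, 1), noise_sd = 0.05,
                                 seed = 1L) {
  set.seed(seed)
  K <- ncol(signature)
  props <- rdirichlet(n_samples, rep_len(alpha, K))
  colnames(props) <- colnames(signature)
  rownames(props) <- sampleIds(n_samples)
  bulk <- signature %*% t(props)
  bulk <- bulk * exp(matrix(rnorm(length(bulk), 0, noise_sd), nrow(bulk)))
  colnames(bulk) <- rownames(props)
  list(bulk = bulk, proportions = props)
}

#' Write a complete, internally consistent fixture bundle to disk
#'
#' Generates expression, sample table, GWAS/eQTL summary statistics, LD,
#' BED gene models (0-based half-open, genes tiled along chromosome 1),
#' BEDPE promoter-interaction pairs, a PPI table, GMT gene sets (one set
#' enriched in each planted module plus random sets), a single-cell
#' reference, and a ground-truth JSON. All files round-trip through the
#' package readers.
#'
#' @param dir output directory (created if missing).
#' @param config a [simConfig()] object.
#' @return invisibly, a named character vector of file paths plus the truth
#'   list as attribute `truth`.
#' @export
writeFixtureBundle <- function(dir, config) {
  validateSimConfig(config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulateExpression(config)
  ss <- simulateSummaryStats(config, shared = TRUE)
  gid <- rownames(SummarizedExperiment::assay(sim$counts))

  # gene models: 10 kb bodies spaced 50 kb apart along chr1
  nG <- length(gid)
  starts <- seq(0L, by = 50000L, length.out = nG)
  genes <- GenomicRanges::GRanges("1",
    IRanges::IRanges(start = starts + 1L, end = starts + 10000L),
    strand = rep(c("+", "-"), length.out = nG))
  names(genes) <- gid
  genes$name <- gid

  # promoter interactions: other-end upstream windows looping to promoters
  set.seed(config$seed + 4000L)
  nInt <- min(200L, nG)
  bi <- sample.int(nG, nInt)
  bedpe <- data.frame(
    chrom1 = "1", start1 = starts[bi], end1 = starts[bi] + 2000L,
    chrom2 = "1", start2 = pmax(0L, starts[bi] - 30000L),
    end2 = pmax(0L, starts[bi] - 30000L) + 5000L,
    name = gid[bi], stringsAsFactors = FALSE)

  labels <- sim$truth$module_label_per_gene
  ppiNodes <- gid[seq_len(min(config$n_ppi_nodes, nG))]
  cfg_ppi <- config
  if (length(ppiNodes) != config$n_ppi_nodes) {
    cfg_ppi$n_ppi_nodes <- length(ppiNodes)
  }
  assoc <- names(labels)[labels %in% sim$truth$assoc_module_ids]
  hubCand <- intersect(assoc, ppiNodes)
  # plant the hub away from the chromosome edge so its cis window holds the
  # full summary-statistic region and it can earn colocalisation evidence
  ppi <- simulatePPI(cfg_ppi, ppiNodes, assoc_genes = hubCand,
                     hub_node = hubCand[min(10L, length(hubCand))])

  # gene sets: one per planted module (75% of its genes) plus random sets
  set.seed(config$seed + 5000L)
  sets <- list()
  for (m in unique(labels[labels > 0L])) {
    mg <- names(labels)[labels == m]
    sets[[sprintf("PLANTED_MODULE_%d", m)]] <-
      sample(mg, max(2L, round(0.75 * length(mg))))
  }
  for (k in 1:5) sets[[sprintf("RANDOM_SET_%d", k)]] <-
    sample(gid, min(50L, nG))

  ref <- simulateSingleCellReference(
    config,
    n_marker_genes = max(5L, min(50L, nG %/% (2L * config$n_celltypes))))

  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    samples = file.path(dir, "samples.tsv"),
    gwas = file.path(dir, "gwas.tsv"),
    eqtl = file.path(dir, "eqtl.tsv"),
    ld = file.path(dir, "ld.tsv"),
    genes = file.path(dir, "genes.bed"),
    interactions = file.path(dir, "interactions.bedpe"),
    ppi = file.path(dir, "ppi.tsv"),
    gmt = file.path(dir, "sets.gmt"),
    reference_counts = file.path(dir, "reference_counts.tsv"),
    reference_labels = file.path(dir, "reference_labels.tsv"),
    truth = file.path(dir, "truth.json")
  )
  writeCounts(SummarizedExperiment::assay(sim$counts), paths["counts"])
  writeSampleTable(sim$samples, paths["samples"])
  writeSummaryStats(ss$gwas, paths["gwas"])
  writeSummaryStats(ss$eqtl, paths["eqtl"])
  writeLDMatrix(ss$ld, paths["ld"])
  writeBed(genes, paths["genes"])
  writeBedpe(bedpe, paths["interactions"])
  writePPITable(ppi$network, paths["ppi"])
  writeGMT(sets, paths["gmt"])
  writeCounts(ref$counts, paths["reference_counts"])
  writeSampleTable(data.frame(cell_id = colnames(ref$counts),
                              cell_type = ref$labels,
                              stringsAsFactors = FALSE),
                   paths["reference_labels"])
  truth <- list(
    module_label_per_gene = as.list(sim$truth$module_label_per_gene),
    assoc_module_ids = sim$truth$assoc_module_ids,
    causal_snp_gwas = ss$truth$causal_gwas,
    causal_snp_eqtl = ss$truth$causal_eqtl,
    shared_causal = ss$truth$shared,
    true_proportions = sim$truth$true_proportions,
    planted_hub_node = ppi$truth$planted_hub_node
  )
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  attr(paths, "truth") <- truth
  invisible(paths)
}
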