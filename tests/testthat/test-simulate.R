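test_that("fixed seed gives byte-identical generator output", {
  cfg <- simConfig(seed = 42, n_genes = 120, module_sizes = c(30L, 30L),
                   n_assoc_modules = 1L, region_n_snps = 60L,
                   n_ppi_nodes = 60L, hub_extra_degree = 5L)
  a <- simulateExpression(cfg)
  b <- simulateExpression(cfg)
  expect_identical(SummarizedExperiment::assay(a$counts),
                   SummarizedExperiment::assay(b$counts))
  expect_identical(a$truth, b$truth)
  s1 <- simulateSummaryStats(cfg, shared = TRUE)
  s2 <- simulateSummaryStats(cfg, shared = TRUE)
  expect_identical(s1$gwas, s2$gwas)
  nodes <- sprintf("N%02d", 1:60)
  expect_identical(ppiEdges(simulatePPI(cfg, nodes)$network),
                   ppiEdges(simulatePPI(cfg, nodes)$network))
})

test_that("simulated counts are non-negative integers with controlled depth", {
  cfg <- simConfig(seed = 7, n_genes = 200, module_sizes = c(40L),
                   n_assoc_modules = 1L)
  sim <- simulateExpression(cfg)
  x <- SummarizedExperiment::assay(sim$counts)
  expect_true(all(x >= 0))
  expect_true(all(x == round(x)))
  # realised library sizes track the configured lognormal within 3 SD
  ls <- log(colSums(x))
  expect_true(all(abs(ls - cfg$library_size_lognorm[1]) <
                    3 * cfg$library_size_lognorm[2] + 0.2))
  # identifiers consistent across outputs
  expect_identical(colnames(x), sim$samples$sample_id)
  expect_identical(rownames(x), names(sim$truth$module_label_per_gene))
})

test_that("within-module correlation tracks the squared loading", {
  # loading 0.8 -> latent pairwise correlation 0.64, mildly attenuated by
  # Poisson noise and covariate variance on the transformed scale
  # modules are a small fraction of the transcriptome, as in real data;
  # otherwise median-of-ratios normalisation absorbs the module factors
  mc <- vapply(1:20, function(s) {
    cfg <- simConfig(seed = s, n_genes = 500, module_sizes = c(50L, 50L),
                     n_assoc_modules = 1L, within_module_cor = 0.8)
    sim <- simulateExpression(cfg)
    tr <- normaliseTransform(filterGenes(sim$counts, 1, 1))
    x <- SummarizedExperiment::assay(tr)
    m1 <- names(sim$truth$module_label_per_gene)[
      sim$truth$module_label_per_gene == 1]
    cc <- cor(t(x[m1, ]))
    mean(cc[upper.tri(cc)])
  }, numeric(1))
  expect_gt(mean(mc), 0.55)
  expect_lt(mean(mc), 0.75)
})

test_that("zero loading gives uncorrelated module genes and zero effect gives no association", {
  cfg <- simConfig(seed = 3, n_genes = 120, module_sizes = c(40L),
                   n_assoc_modules = 1L, within_module_cor = 0,
                   factor_effect = 0)
  sim <- simulateExpression(cfg)
  tr <- normaliseTransform(filterGenes(sim$counts, 1, 1))
  x <- SummarizedExperiment::assay(tr)
  m1 <- names(sim$truth$module_label_per_gene)[
    sim$truth$module_label_per_gene == 1]
  cc <- cor(t(x[m1, ]))
  expect_lt(abs(mean(cc[upper.tri(cc)])), 0.1)
  # under factor_effect = 0 the module profile is unlinked to phenotype
  r <- vapply(1:20, function(s) {
    cfg <- simConfig(seed = s, n_genes = 100, module_sizes = c(40L),
                     n_assoc_modules = 1L, factor_effect = 0,
                     within_module_cor = 0.9)
    sim <- simulateExpression(cfg)
    tr <- normaliseTransform(filterGenes(sim$counts, 1, 1))
    x <- SummarizedExperiment::assay(tr)
    m1 <- names(sim$truth$module_label_per_gene)[
      sim$truth$module_label_per_gene == 1]
    prof <- colMeans(t(scale(t(x[m1, ]))))   # per-sample module profile
    abs(cor(prof, sim$samples$phenotype))
  }, numeric(1))
  expect_lt(mean(r), 2 / sqrt(43) + 0.1)   # sampling noise scale for n = 43
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(n_genes = 50, module_sizes = c(30L, 30L)),
               "module_sizes")
  expect_error(simConfig(ld_decay = 1), "ld_decay")
  expect_error(simConfig(within_module_cor = 1), "within_module_cor")
  expect_error(simulateSummaryStats(
    simConfig(n_genes = 50, module_sizes = 10L, n_assoc_modules = 1L,
              region_n_snps = 1L)), "region_n_snps")
})

test_that("PPI generator plants the hub and matches the binomial degree", {
  nodes <- sprintf("N%03d", 1:100)
  cfg <- simConfig(seed = 1, n_genes = 100, module_sizes = 20L,
                   n_assoc_modules = 1L, n_ppi_nodes = 100L,
                   ppi_edge_prob = 0, hub_extra_degree = 5L)
  out <- simulatePPI(cfg, nodes)
  deg <- induced <- table(unlist(ppiEdges(out$network)[, 1:2]))
  expect_identical(as.integer(deg[out$truth$planted_hub_node]), 5L)
  expect_true(all(deg[setdiff(names(deg), out$truth$planted_hub_node)] <= 1))
  # mean degree of the pure Erdos-Renyi graph ~ (n-1) p
  md <- vapply(1:20, function(s) {
    cfg <- simConfig(seed = s, n_genes = 100, module_sizes = 20L,
                     n_assoc_modules = 1L, n_ppi_nodes = 500L,
                     ppi_edge_prob = 0.01, hub_extra_degree = 0L)
    net <- simulatePPI(cfg, sprintf("N%03d", 1:500))$network
    2 * nrow(ppiEdges(net)) / 500
  }, numeric(1))
  expect_lt(abs(mean(md) - 499 * 0.01), 0.25)
})

test_that("summary-statistic regions carry the causal structure and LD", {
  cfg <- simConfig(seed = 9, n_genes = 60, module_sizes = 20L,
                   n_assoc_modules = 1L, region_n_snps = 80L, ld_decay = 0.9)
  sh <- simulateSummaryStats(cfg, shared = TRUE)
  expect_identical(sh$truth$causal_gwas, sh$truth$causal_eqtl)
  di <- simulateSummaryStats(cfg, shared = FALSE)
  expect_gte(abs(match(di$truth$causal_eqtl, di$eqtl$snp) -
                 match(di$truth$causal_gwas, di$gwas$snp)), 10L)
  expect_equal(sh$ld[1, 3], 0.9^2, tolerance = 1e-12)
  expect_equal(unname(sh$gwas$se),
               1 / sqrt(2 * sh$gwas$n * sh$gwas$maf * (1 - sh$gwas$maf)),
               tolerance = 1e-12)
  # strongest signal sits at/near the causal SNP
  expect_lt(abs(which.max(abs(sh$gwas$beta / sh$gwas$se)) -
                match(sh$truth$causal_gwas, sh$gwas$snp)), 5)
})

test_that("fixture bundle round-trips through the package readers", {
  dir <- withr::local_tempdir()
  cfg <- simConfig(seed = 11, n_genes = 150, module_sizes = c(40L, 30L),
                   n_assoc_modules = 1L, region_n_snps = 60L,
                   n_ppi_nodes = 100L, hub_extra_degree = 8L)
  paths <- writeFixtureBundle(dir, cfg)
  expect_true(all(file.exists(paths)))
  # write -> read -> write is byte-identical
  counts <- readCounts(paths[["counts"]])
  p2 <- file.path(dir, "counts2.tsv")
  writeCounts(counts, p2)
  expect_identical(unname(tools::md5sum(p2)),
                   unname(tools::md5sum(paths[["counts"]])))
  ss <- readSummaryStats(paths[["gwas"]], "cc")
  p3 <- file.path(dir, "gwas2.tsv")
  writeSummaryStats(ss, p3)
  expect_identical(unname(tools::md5sum(p3)),
                   unname(tools::md5sum(paths[["gwas"]])))
  # identifier namespaces are consistent across files
  truth <- attr(paths, "truth")
  expect_true(all(readSampleTable(paths[["samples"]])$sample_id
                  %in% colnames(counts)))
  expect_true(all(ppiNodes(readPPITable(paths[["ppi"]])) %in%
                    rownames(counts)))
  expect_true(all(unlist(readGMT(paths[["gmt"]])) %in% rownames(counts)))
  expect_true(truth$planted_hub_node %in% rownames(counts))
  # regenerating under the same seed reproduces identical files
  dir2 <- withr::local_tempdir()
  paths2 <- writeFixtureBundle(dir2, cfg)
  expect_identical(unname(tools::md5sum(paths)),
                   unname(tools::md5sum(paths2)))
})

test_that("single-cell reference has marker structure and supports mixtures", {
  cfg <- simConfig(seed = 5, n_genes = 400, module_sizes = 50L,
                   n_assoc_modules = 1L, n_celltypes = 3L,
                   dirichlet_alpha = c(5, 3, 2))
  ref <- simulateSingleCellReference(cfg, n_cells_per_type = 30L)
  expect_identical(ncol(ref$counts), 90L)
  sig <- buildSignature(ref$counts, ref$labels)
  # empirical type means approach the configured profiles (CPM scale)
  tm <- ref$truth$type_means_cpm
  expect_gt(cor(log1p(sig[, 1]), log1p(tm[, 1])), 0.95)
  mix <- simulateBulkMixtures(sig, n_samples = 5, alpha = c(5, 3, 2),
                              noise_sd = 0, seed = 2)
  expect_equal(unname(rowSums(mix$proportions)), rep(1, 5),
               tolerance = 1e-12)
})
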