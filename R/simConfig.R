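#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generators. Defaults emulate
#' the study design the pipeline targets: 32 cases and 11 controls of bulk
#' CD4+ T-cell 3'-RNA-seq, block co-expression structure with a few modules
#' whose latent factors shift with case status, covariate effects (sex, batch,
#' PCR cycles, cell proportions), cis regions with realistic AR(1) LD, and an
#' Erdos-Renyi PPI graph with an optional planted hub.
#'
#' `within_module_cor` is the gene-factor loading: two genes of the same
#' module then correlate at loading squared on the latent scale.
#' `factor_effect` is the standardised mean shift of the latent module factor
#' between cases and controls (the factor has unit variance, so the shift is
#' in SD units). `library_size_lognorm` gives (meanlog, sdlog) of the library
#' size; the default meanlog is derived so mean depth is ~100 counts/gene.
#' The GWAS/eQTL standard errors use the standard approximation
#' `se = 1/sqrt(2 N maf (1-maf))`.
#'
#' @param seed integer RNG seed; every generator call seeds once from it and
#'   derives per-dataset sub-streams deterministically.
#' @param n_cases,n_controls sample counts per group.
#' @param n_genes total genes simulated.
#' @param module_sizes integer vector of planted module sizes (first blocks of
#'   genes); remaining genes are independent background noise.
#' @param n_assoc_modules how many leading modules shift with case status.
#' @param factor_effect standardised case-control shift of the module factor.
#' @param within_module_cor gene-factor loading in (0, 1).
#' @param library_size_lognorm length-2 numeric (meanlog, sdlog) of library
#'   size; `NULL` derives meanlog = log(600 * n_genes), sdlog = 0.2 — about
#'   the depth of an 8M-read library over ~13k expressed genes.
#' @param covariate_effects named numeric SDs of per-gene covariate
#'   coefficients on the log-expression scale (sex, batch, pcr, celltype).
#' @param n_celltypes number of cell types in the single-cell reference.
#' @param dirichlet_alpha Dirichlet concentration for true cell proportions;
#'   scalar or length `n_celltypes`.
#' @param region_n_snps SNPs per simulated summary-statistic region.
#' @param ld_decay AR(1) genotype correlation between adjacent SNPs, in [0,1).
#' @param eqtl_beta,gwas_beta causal effect sizes for the two traits.
#' @param sumstat_n GWAS/eQTL sample size entering the se approximation.
#' @param n_ppi_nodes,ppi_edge_prob,hub_extra_degree PPI generator: node
#'   count, Erdos-Renyi edge probability, and number of extra edges attached
#'   to the planted hub (0 disables the planting).
#' @return a validated `SimConfig` object (list with class attribute).
#' @export
simConfig <- function(seed = 1L,
                      n_cases = 32L, n_controls = 11L,
                      n_genes = 10000L,
                      module_sizes = c(300L, 250L, 200L, 150L),
                      n_assoc_modules = 3L,
                      factor_effect = 1.0,
                      within_module_cor = 0.8,
                      library_size_lognorm = NULL,
                      covariate_effects = c(sex = 0.1, batch = 0.1,
                                            pcr = 0.05, celltype = 0.3),
                      n_celltypes = 4L,
                      dirichlet_alpha = c(8, 5, 3, 1),
                      region_n_snps = 200L,
                      ld_decay = 0.9,
                      eqtl_beta = 0.5, gwas_beta = 0.5,
                      sumstat_n = 10000L,
                      n_ppi_nodes = 400L,
                      ppi_edge_prob = 0.05,
                      hub_extra_degree = 30L) {
  if (is.null(library_size_lognorm))
    library_size_lognorm <- c(meanlog = log(600 * n_genes), sdlog = 0.2)
  cfg <- list(
    seed = as.integer(seed),
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_genes = as.integer(n_genes),
    module_sizes = as.integer(module_sizes),
    n_assoc_modules = as.integer(n_assoc_modules),
    factor_effect = factor_effect,
    within_module_cor = within_module_cor,
    library_size_lognorm = as.numeric(library_size_lognorm),
    covariate_effects = covariate_effects,
    n_celltypes = as.integer(n_celltypes),
    dirichlet_alpha = as.numeric(dirichlet_alpha),
    region_n_snps = as.integer(region_n_snps),
    ld_decay = ld_decay,
    eqtl_beta = eqtl_beta, gwas_beta = gwas_beta,
    sumstat_n = as.integer(sumstat_n),
    n_ppi_nodes = as.integer(n_ppi_nodes),
    ppi_edge_prob = ppi_edge_prob,
    hub_extra_degree = as.integer(hub_extra_degree)
  )
  class(cfg) <- "SimConfig"
  validateSimConfig(cfg)
  cfg
}

validateSimConfig <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  counts <- c(cfg$n_cases, cfg$n_controls, cfg$n_genes, cfg$n_celltypes,
              cfg$region_n_snps, cfg$n_ppi_nodes, cfg$sumstat_n)
  if (any(counts <= 0L)) stop("all counts in SimConfig must be > 0")
  if (any(cfg$module_sizes <= 0L)) stop("module_sizes must be > 0")
  if (sum(cfg$module_sizes) > cfg$n_genes)
    stop("configuration error: sum(module_sizes) exceeds n_genes")
  if (cfg$n_assoc_modules > length(cfg$module_sizes))
    stop("n_assoc_modules exceeds the number of modules")
  if (cfg$within_module_cor < 0 || cfg$within_module_cor >= 1)
    stop("within_module_cor must lie in [0, 1)")
  if (cfg$ld_decay < 0 || cfg$ld_decay >= 1)
    stop("ld_decay must lie in [0, 1)")
  if (cfg$ppi_edge_prob < 0 || cfg$ppi_edge_prob > 1)
    stop("ppi_edge_prob must lie in [0, 1]")
  if (!length(cfg$dirichlet_alpha) %in% c(1L, cfg$n_celltypes))
    stop("dirichlet_alpha must be scalar or length n_celltypes")
  invisible(cfg)
}
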