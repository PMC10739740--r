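mkModuleSetForTop <- function(seed = 1, nGenes = 100) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(nGenes))
  labels <- setNames(rep(1L, nGenes), genes)
  mm <- matrix(runif(nGenes), nGenes, 1, dimnames = list(genes, "ME1"))
  gs <- setNames(runif(nGenes, -1, 1), genes)
  ms <- ModuleSet(genes, labels, membership = mm, significance = gs)
  ms@assocModules <- 1L
  ms
}

test_that("top-gene set follows union semantics over coloc and MM/GS deciles", {
  ms <- mkModuleSetForTop()
  # quantiles 0: every module gene is included
  cfg0 <- topGeneConfig(mm_quantile = 0, gs_quantile = 0,
                        n_permutations = 100L)
  top0 <- buildTopGeneSet(setNames(numeric(0), character(0)), ms, cfg0)
  expect_identical(top0$gene, sort(ms@genes))
  # independent MM and GS ranks: selected set equals the brute-force
  # rank intersection
  cfg <- topGeneConfig(n_permutations = 100L)
  top <- buildTopGeneSet(setNames(numeric(0), character(0)), ms, cfg)
  mm <- ms@membership[, 1]
  gs <- abs(ms@significance)
  bf <- intersect(names(mm)[mm >= quantile(mm, 0.9)],
                  names(gs)[gs >= quantile(gs, 0.9)])
  expect_setequal(top$gene, bf)
  expect_lte(nrow(top), 12L)   # ~ nGenes * 0.1 * 0.1 under independence
  # a gene with PP4 just above threshold enters via criterion 1 alone
  low <- setdiff(ms@genes, bf)[1]
  top2 <- buildTopGeneSet(setNames(0.51, low), ms, cfg)
  expect_true(low %in% top2$gene)
  expect_true(top2$coloc[top2$gene == low])
  expect_false(top2$mm_gs[top2$gene == low])
  # intersect operator empties the set when the lists are disjoint
  cfgI <- topGeneConfig(operator = "intersect", n_permutations = 100L)
  topI <- buildTopGeneSet(setNames(0.9, low), ms, cfgI)
  expect_false(low %in% topI$gene)
  # no associated modules recorded -> error
  ms2 <- mkModuleSetForTop()
  ms2@assocModules <- integer(0)
  expect_error(buildTopGeneSet(setNames(numeric(0), character(0)), ms2,
                               cfg), "associated")
})

test_that("score recombination is a prior-corrected noisy-OR", {
  # single channel, no exclusions: identity within 1e-12
  for (s in c(0.15, 0.4, 0.7, 0.95)) {
    m <- matrix(0, 1, 7,
                dimnames = list(NULL, c("experiments", "database",
                                        "textmining", "coexpression",
                                        "neighbourhood", "fusion",
                                        "cooccurrence")))
    m[1, "experiments"] <- s
    expect_equal(combineChannelScores(m), s, tolerance = 1e-12)
  }
  # two channels at 0.9: independent evaluation of the formula
  m2 <- matrix(0, 1, 7, dimnames = dimnames(matrix(0, 1, 7,
    dimnames = list(NULL, c("experiments", "database", "textmining",
                            "coexpression", "neighbourhood", "fusion",
                            "cooccurrence")))))
  m2[1, c(1, 2)] <- 0.9
  pr <- 0.041
  sp <- (0.9 - pr) / (1 - pr)
  manual <- (1 - (1 - sp)^2) * (1 - pr) + pr
  expect_equal(combineChannelScores(m2, pr), manual, tolerance = 1e-12)
  # excluding every channel leaves only the prior and the edge is dropped
  ed <- toyPPI(cbind("a", "b"), score = 0.95, channel = "coexpression")
  out <- recombineScores(ed, exclusions = c("experiments", "database",
    "textmining", "coexpression", "neighbourhood", "fusion", "cooccurrence"))
  expect_identical(nrow(ppiEdges(out)), 0L)
  # an edge supported only by an excluded channel disappears at the default
  # exclusions; an experiments-supported edge survives
  net <- toyPPI(rbind(c("a", "b"), c("b", "c")), score = 0.9)
  net@edges[2, "experiments"] <- 0
  net@edges[2, "coexpression"] <- 0.9
  net@edges$combined <- combineChannelScores(
    as.matrix(net@edges[, c("experiments", "database", "textmining",
                            "coexpression", "neighbourhood", "fusion",
                            "cooccurrence")]))
  out2 <- recombineScores(net)
  expect_identical(nrow(ppiEdges(out2)), 1L)
  expect_identical(ppiEdges(out2)$protein1, "a")
})

test_that("hub statistic counts induced degrees with lexicographic ties", {
  # edgeless set
  net <- toyPPI(cbind("x", "y"), nodes = c("a", "b", "c", "x", "y"))
  expect_identical(hubStatistic(net, c("a", "b", "c"))$max_degree, 0L)
  # star graph: the centre is the hub at degree |set| - 1
  star <- toyPPI(cbind("hub", paste0("n", 1:6)))
  hs <- hubStatistic(star, c("hub", paste0("n", 1:6)))
  expect_identical(hs$hub, "hub")
  expect_identical(hs$max_degree, 6L)
  # degrees equal a brute-force incidence count; ties lexicographic
  set.seed(151)
  nodes <- sprintf("n%02d", 1:15)
  pairs <- t(combn(nodes, 2))
  pairs <- pairs[runif(nrow(pairs)) < 0.3, ]
  net2 <- toyPPI(pairs, nodes = nodes)
  sub <- nodes[1:10]
  hs2 <- hubStatistic(net2, sub)
  ed <- ppiEdges(net2)
  bf <- vapply(sub, function(v) sum((ed$protein1 == v & ed$protein2 %in% sub) |
                                    (ed$protein2 == v & ed$protein1 %in% sub)),
               integer(1))
  expect_identical(hs2$degrees[sub], bf)
  expect_identical(hs2$hub, sort(names(bf)[bf == max(bf)])[1])
})

test_that("permutation p uses add-one smoothing and detects a planted hub", {
  # observed above all B = 99 permutation maxima -> p = 1/100
  net <- toyPPI(cbind("a", "b"),
                nodes = c("a", "b", sprintf("n%02d", 1:30)))
  pt <- permutationTest(net, sprintf("n%02d", 1:30), 5, observed = 10,
                        n_permutations = 99L, seed = 1)
  expect_equal(pt$p, 0.01)
  expect_gt(pt$p, 0)
  # monotone non-increasing in the observed statistic
  p_lo <- permutationTest(net, sprintf("n%02d", 1:30), 5, observed = 0,
                          n_permutations = 99L, seed = 1)$p
  expect_gte(p_lo, pt$p)
  # set size larger than the universe errors
  expect_error(permutationTest(net, c("a", "b"), 5, 1, 100L), "universe")
  # planted hub whose extra edges lie inside the candidate set
  cfg <- simConfig(seed = 3, n_genes = 400, module_sizes = c(60L, 60L),
                   n_assoc_modules = 2L, n_ppi_nodes = 400L,
                   ppi_edge_prob = 0.05, hub_extra_degree = 25L)
  nodes <- sprintf("G%05d", 1:400)
  assoc <- nodes[1:120]
  set.seed(99)
  topset <- c(assoc[1], sample(assoc[-1], 29))
  ppi <- simulatePPI(cfg, nodes, assoc_genes = topset, hub_node = assoc[1])
  net2 <- recombineScores(ppi$network)
  hs <- hubStatistic(net2, topset)
  expect_identical(hs$hub, ppi$truth$planted_hub_node)
  pt2 <- permutationTest(net2, assoc, 30, hs$max_degree,
                         n_permutations = 2000L, seed = 5)
  expect_lte(pt2$p, 0.01)
})

test_that("permutation statistics are invariant to node relabelling", {
  set.seed(161)
  nodes <- sprintf("n%02d", 1:20)
  pairs <- t(combn(nodes, 2))
  pairs <- pairs[runif(nrow(pairs)) < 0.25, ]
  net <- toyPPI(pairs, nodes = nodes)
  pt <- permutationTest(net, nodes, 8, observed = 3,
                        n_permutations = 500L, seed = 7)
  # relabel nodes by a fixed permutation
  perm <- setNames(sprintf("m%02d", sample(20)), nodes)
  ed <- ppiEdges(net)
  ed$protein1 <- unname(perm[ed$protein1])
  ed$protein2 <- unname(perm[ed$protein2])
  sw <- ed$protein1 > ed$protein2
  tmp <- ed$protein1[sw]; ed$protein1[sw] <- ed$protein2[sw]
  ed$protein2[sw] <- tmp
  net2 <- PPINetwork(unname(perm), ed)
  pt2 <- permutationTest(net2, unname(perm[nodes]), 8, observed = 3,
                         n_permutations = 500L, seed = 7)
  # same seed, same universe ordering under the relabelling: same p
  expect_equal(sort(pt$perm_stats), sort(pt2$perm_stats))
  expect_equal(pt$p, pt2$p)
})
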