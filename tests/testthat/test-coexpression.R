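test_that("signed-hybrid adjacency zeroes negatives and powers positives", {
  cc <- matrix(c(1, 0.5, -0.5,
                 0.5, 1, 1,
                 -0.5, 1, 1), 3, 3)
  a <- signedHybridAdjacency(cc, 6)
  expect_equal(a[1, 2], 0.5^6)       # 1/64
  expect_equal(a[1, 2], 0.015625)
  expect_equal(a[1, 3], 0)
  expect_equal(a[2, 3], 1)
  expect_equal(diag(a), c(0, 0, 0))
  expect_error(signedHybridAdjacency(matrix(c(1, 0.2, 0.3, 1), 2, 2), 6),
               "symmetric")
})

test_that("TOM matches hand evaluation and the brute-force oracle", {
  # zero adjacency -> identity
  z <- matrix(0, 4, 4)
  expect_equal(tomSimilarity(z), diag(4))
  # 3 nodes all 0.5: TOM_12 = (0.25 + 0.5) / (1 + 1 - 0.5) = 0.5
  a <- matrix(0.5, 3, 3); diag(a) <- 0
  expect_equal(tomSimilarity(a)[1, 2], 0.5)
  # random instances against the element-wise oracle
  for (s in 1:20) {
    n <- sample(5:25, 1)
    a <- randomAdjacency(n, s)
    tom <- tomSimilarity(a)
    expect_lt(max(abs(tom - tomOracle(a))), 1e-12)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_equal(tom, t(tom), tolerance = 1e-12)
  }
  expect_error(tomSimilarity(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
})

test_that("soft-threshold report is well-formed and honours the default power", {
  expect_identical(networkParams()$beta, 6L)
  set.seed(31)
  # heterogeneous block sizes give a right-skewed connectivity distribution
  sizes <- c(40, 20, 12, 8, 6, 4)
  n <- 43
  x <- do.call(rbind, lapply(seq_along(sizes), function(i) {
    f <- rnorm(n)
    0.85 * matrix(f, sizes[i], n, byrow = TRUE) +
      sqrt(1 - 0.85^2) * matrix(rnorm(sizes[i] * n), sizes[i], n)
  }))
  dimnames(x) <- list(sprintf("g%03d", seq_len(nrow(x))),
                      sprintf("S%02d", 1:n))
  rep <- suppressWarnings(pickSoftThreshold(x, candidates = 1:12))
  expect_true(all(rep$table$r2 >= 0 & rep$table$r2 <= 1))
  expect_true(all(diff(rep$table$mean_k) < 0))   # connectivity shrinks in beta
  expect_true(rep$chosen %in% 1:12)
  # perfectly modular structure is degenerate: smallest candidate returned
  xb <- rbind(matrix(rep(rnorm(10), 30), 30, 10, byrow = TRUE),
              matrix(rep(rnorm(10), 30), 30, 10, byrow = TRUE))
  dimnames(xb) <- list(sprintf("g%02d", 1:60), sprintf("S%02d", 1:10))
  repb <- suppressWarnings(pickSoftThreshold(xb, candidates = 2:8))
  expect_identical(repb$chosen, 2L)
})

test_that("module detection recovers planted blocks and ignores noise", {
  # two perfect 50-gene blocks at loading ~0.95
  set.seed(41)
  n <- 43
  mk <- function(sz, lam) {
    f <- rnorm(n)
    lam * matrix(f, sz, n, byrow = TRUE) +
      sqrt(1 - lam^2) * matrix(rnorm(sz * n), sz, n)
  }
  x <- rbind(mk(50, 0.95), mk(50, 0.95), matrix(rnorm(30 * n), 30, n))
  dimnames(x) <- list(sprintf("g%03d", 1:130), sprintf("S%02d", 1:n))
  truth <- rep(c(1, 2, 0), c(50, 50, 30))
  ms <- buildNetwork(x)
  expect_gte(ariOracle(truth[truth > 0], moduleLabels(ms)[truth > 0]), 0.9)
  # pure noise: >= 90% unassigned at defaults
  un <- vapply(1:5, function(s) {
    xs <- makeMatrix(150, 43, seed = s)
    mean(moduleLabels(buildNetwork(xs)) == 0)
  }, numeric(1))
  expect_true(all(un >= 0.9))
  # min_module_size larger than any cluster leaves everything unassigned
  msBig <- detectModules(tomSimilarity(signedHybridAdjacency(cor(t(x)), 6)),
                         x, networkParams(min_module_size = 200L))
  expect_true(all(moduleLabels(msBig) == 0L))
})

test_that("eigengenes equal the first principal component up to sign", {
  # single-gene module: eigengene is the standardised gene, correlation +1
  x <- makeMatrix(10, 20, seed = 51)
  me1 <- moduleEigengenes(x, c(1L, rep(0L, 9)))
  expect_equal(abs(cor(me1[, 1], x[1, ])), 1, tolerance = 1e-12)
  expect_gt(cor(me1[, 1], x[1, ]), 0)
  # module of identical genes: eigengene proportional to the shared profile
  xid <- rbind(matrix(rep(x[1, ], 5), 5, 20, byrow = TRUE), x[6:10, ])
  rownames(xid) <- rownames(x)
  meid <- moduleEigengenes(xid, c(rep(1L, 5), rep(0L, 5)))
  expect_equal(abs(cor(meid[, 1], x[1, ])), 1, tolerance = 1e-12)
  # random modules against an independent eigendecomposition
  for (s in 1:10) {
    xm <- makeMatrix(30, 15, seed = 60 + s)
    me <- moduleEigengenes(xm, rep(1L, 30))
    ev <- eigen(crossprod(t(scale(t(xm)))))$vectors[, 1]
    expect_gt(abs(cor(me[, 1], ev)), 1 - 1e-10)
    expect_equal(sum(me[, 1]^2), 1, tolerance = 1e-10)   # unit norm
  }
})

test_that("module membership and gene significance are plain correlations", {
  x <- makeMatrix(20, 25, seed = 71)
  labels <- rep(1L, 20)
  me <- moduleEigengenes(x, labels)
  x2 <- rbind(x, ME = as.numeric(me[, 1]))
  mm <- moduleMembership(x2, me)
  expect_equal(unname(mm["ME", 1]), 1, tolerance = 1e-12)
  pheno <- rep(c(1, 0), c(15, 10))
  x3 <- rbind(x, P = pheno)
  gs <- geneSignificance(x3, pheno)
  expect_equal(unname(gs["P"]), 1, tolerance = 1e-12)
  # null GS stays small for n = 43
  gsn <- geneSignificance(makeMatrix(500, 43, seed = 72),
                          rep(c(1, 0), c(32, 11)))
  expect_gt(mean(abs(gsn) < 0.5), 0.99)
})

test_that("module merging is threshold-faithful and idempotent", {
  set.seed(81)
  n <- 30
  f <- rnorm(n)
  lam <- 0.9
  mk <- function(sz, fac) lam * matrix(fac, sz, n, byrow = TRUE) +
    sqrt(1 - lam^2) * matrix(rnorm(sz * n), sz, n)
  # modules 1 and 2 share a factor (duplicated module); module 3 independent
  x <- rbind(mk(20, f), mk(20, f), mk(20, rnorm(n)))
  dimnames(x) <- list(sprintf("g%02d", 1:60), sprintf("S%02d", 1:n))
  labels <- setNames(rep(1:3, each = 20), rownames(x))
  ms0 <- ModuleSet(rownames(x), labels,
                   eigengenes = moduleEigengenes(x, labels))
  merged <- mergeModules(x, ms0, merge_cor = 0.75)
  expect_identical(length(unique(moduleLabels(merged)[1:40])), 1L)
  expect_identical(length(unique(moduleLabels(merged))), 2L)
  # merge_cor = 1 never merges
  expect_identical(
    length(unique(moduleLabels(mergeModules(x, ms0, merge_cor = 1)))), 3L)
  # idempotence
  merged2 <- mergeModules(x, merged, merge_cor = 0.75)
  expect_identical(moduleLabels(merged2), moduleLabels(merged))
})
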