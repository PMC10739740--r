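# Independent brute-force oracles, kept deliberately naive and separate from
# the implementation paths they check.

# TOM by direct evaluation of the formula, element by element
tomOracle <- function(a) {
  n <- nrow(a)
  diag(a) <- 0
  out <- matrix(0, n, n)
  k <- rowSums(a)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { out[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(n)) l <- l + a[i, u] * a[u, j]
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# coloc posteriors by explicit (i, j) enumeration on the plain ABF scale
colocOracle <- function(l1, l2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  b1 <- exp(l1); b2 <- exp(l2)
  S1 <- sum(b1); S2 <- sum(b2)
  S12 <- sum(b1 * b2)
  S3 <- 0
  for (i in seq_along(b1)) for (j in seq_along(b2))
    if (i != j) S3 <- S3 + b1[i] * b2[j]
  h <- c(1, p1 * S1, p2 * S2, p1 * p2 * S3, p12 * S12)
  setNames(h / sum(h), c("PP0", "PP1", "PP2", "PP3", "PP4"))
}

# hypergeometric upper tail by explicit counting: subset enumeration for
# small instances, factorial sums otherwise (never phyper)
hyperOracle <- function(n_overlap, set_size, module_size, universe_size) {
  if (choose(universe_size, module_size) <= 2e4) {
    draws <- combn(universe_size, module_size)
    hits <- colSums(draws <= set_size)   # treat 1..set_size as the set
    mean(hits >= n_overlap)
  } else {
    kmax <- min(set_size, module_size)
    tot <- 0
    for (k in n_overlap:kmax)
      tot <- tot + choose(set_size, k) *
        choose(universe_size - set_size, module_size - k)
    tot / choose(universe_size, module_size)
  }
}

# BH step-up by direct evaluation of the definition
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (r in seq_len(m)) {
    vals <- numeric(0)
    for (s in r:m) vals <- c(vals, p[o[s]] * m / s)
    q[o[r]] <- min(1, vals)
  }
  q
}

# one-covariate logistic regression by hand-rolled IRLS
irlsLogistic <- function(y, x, maxit = 50L) {
  X <- cbind(1, x)
  b <- c(0, 0)
  for (it in seq_len(maxit)) {
    eta <- X %*% b
    mu <- 1 / (1 + exp(-eta))
    W <- as.vector(mu * (1 - mu))
    z <- eta + (y - mu) / W
    b_new <- solve(t(X) %*% (X * W), t(X) %*% (z * W))
    if (max(abs(b_new - b)) < 1e-10) { b <- b_new; break }
    b <- b_new
  }
  vc <- solve(t(X) %*% (X * as.vector(mu * (1 - mu))))
  list(beta = b[2], se = sqrt(vc[2, 2]))
}

randomAdjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  a
}

makeMatrix <- function(n_genes, n_samples, seed = 1, mean = 0) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples, mean = mean), n_genes, n_samples,
         dimnames = list(sprintf("G%04d", seq_len(n_genes)),
                         sprintf("S%03d", seq_len(n_samples))))
}

# adjusted Rand index (self-contained so the suite does not require mclust)
ariOracle <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sn <- choose(sum(tab), 2)
  exp_ij <- si * sj / sn
  (sij - exp_ij) / ((si + sj) / 2 - exp_ij)
}

# toy PPI edge table with all channels at given scores
toyPPI <- function(edges, nodes = NULL, score = 0.9, channel = "experiments") {
  ch <- c("experiments", "database", "textmining", "coexpression",
          "neighbourhood", "fusion", "cooccurrence")
  ed <- data.frame(protein1 = edges[, 1], protein2 = edges[, 2],
                   stringsAsFactors = FALSE)
  for (c0 in ch) ed[[c0]] <- 0
  ed[[channel]] <- score
  ed$combined <- combineChannelScores(as.matrix(ed[, ch]))
  if (is.null(nodes)) nodes <- sort(unique(c(ed$protein1, ed$protein2)))
  PPINetwork(nodes, ed)
}
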