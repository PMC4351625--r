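# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the Fisher oracle enumerates hypergeometric
# probabilities from log-binomial coefficients, the scatter oracle builds
# H and E by explicit loops, and the Ward oracle scores partitions
# directly.

# exhaustive two-sided Fisher p by enumeration over all tables with the
# observed margins (lchoose-based; the implementation uses dhyper)
fisherOracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; K <- a + c
  ks <- max(0, K - m2):min(K, m1)
  logp <- lchoose(m1, ks) + lchoose(m2, K - ks) - lchoose(m1 + m2, K)
  obs <- lchoose(m1, a) + lchoose(m2, K - a) - lchoose(m1 + m2, K)
  min(1, sum(exp(logp)[logp <= obs + log1p(1e-7)]))
}

# vectorized variant for large enumerations
fisherOracleVec <- function(a, b, c, d) {
  mapply(fisherOracle, a, b, c, d)
}

# between/within scatter by explicit per-observation loops
scatterOracle <- function(X, labels) {
  X <- as.matrix(X)
  p <- ncol(X)
  grand <- colMeans(X)
  H <- matrix(0, p, p); E <- matrix(0, p, p)
  for (g in unique(labels)) {
    Xg <- X[labels == g, , drop = FALSE]
    mg <- colMeans(Xg)
    H <- H + nrow(Xg) * outer(mg - grand, mg - grand)
    for (i in seq_len(nrow(Xg)))
      E <- E + outer(Xg[i, ] - mg, Xg[i, ] - mg)
  }
  list(H = H, E = E)
}

# total within-cluster sum of squares of a partition (the Ward objective)
withinSS <- function(coords, labels) {
  coords <- as.matrix(coords)
  sum(vapply(unique(labels), function(g) {
    Xg <- coords[labels == g, , drop = FALSE]
    sum(sweep(Xg, 2, colMeans(Xg))^2)
  }, numeric(1)))
}

# all partitions of n items into at most k non-empty blocks
allPartitions <- function(n, k) {
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  keep <- apply(grid, 1, function(z) length(unique(z)) == k)
  grid[keep, , drop = FALSE]
}

# tiny single-chromosome MethylomeExperiment from count vectors/matrices
makeME <- function(pos, context, meth, cov, chrom = "Chr1", strand = "+",
                   samples = NULL) {
  meth <- as.matrix(meth); cov <- as.matrix(cov)
  if (is.null(samples))
    samples <- colnames(meth)
  if (is.null(samples))
    samples <- paste0("s", seq_len(ncol(meth)))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1),
                               strand = strand, context = context)
  MethylomeExperiment(meth, cov, gr, sampleNames = samples)
}

# fast small simulation config shared by several tests
smallConfig <- function(...) {
  args <- list(nChroms = 1L, chromLength = 2e5,
               pericentromereHalfwidth = 5e4, nGenes = 25L,
               nTransposons = 25L, nIslands = 8L,
               siteDensity = c(CG = 0.004, CHG = 0.002, CHH = 0.004),
               samplesPerGroup = c(wildtype = 2L, mutant = 2L,
                                   epiline = 2L))
  over <- list(...)
  args[names(over)] <- over
  do.call(simulationConfig, args)
}
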