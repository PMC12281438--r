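# Independent brute-force oracles used to cross-check the package's
# statistics on small fixtures. Deliberately naive implementations.

# Benjamini-Hochberg step-up, coded from the definition
oracleBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Kruskal-Wallis statistic from pooled ranks with tie correction
oracleKW <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * mean(ri)^2)) -
    3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# exact two-sided one-sample signed-rank p by enumeration of sign vectors
oracleSignedRankP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  stats <- signs %*% r
  mu <- n * (n + 1) / 4
  min(1, 2 * min(mean(stats >= obs), mean(stats <= obs)))
}

# exact two-sided rank-sum p by enumeration of group assignments
oracleRankSumP <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  nx <- length(x)
  obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(length(pooled), nx)
  stats <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * length(y) / 2
  min(1, 2 * min(mean(stats >= obs), mean(stats <= obs)))
}

# sampled permutation p for |spearman rho|
oracleSpearmanPermP <- function(x, y, B = 20000, seed = 99) {
  obs <- abs(cor(x, y, method = "spearman"))
  ibrd:::withSeed(seed, {
    perm <- replicate(B, abs(cor(x, sample(y), method = "spearman")))
    mean(perm >= obs - 1e-12)
  })
}

# median-of-ratios size factors from the definition
oracleSizeFactors <- function(counts) {
  ref <- apply(counts, 1, function(g) all(g > 0))
  geo <- apply(counts[ref, , drop = FALSE], 1, function(g) prod(g)^(1 / length(g)))
  apply(counts[ref, , drop = FALSE], 2, function(col) median(col / geo))
}

# per-sample richness and Shannon-effective from the entropy definition
oracleAlpha <- function(counts) {
  t(apply(counts, 2, function(col) {
    p <- col[col > 0] / sum(col)
    c(richness = sum(col > 0), shannon = exp(-sum(p * log(p))))
  }))
}
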