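# Independent oracles, coded straight from definitions; they deliberately
# share no code with the package internals.

# rank product via per-gene, per-comparison loops
oracle_rank_product <- function(changes, direction) {
  n <- nrow(changes)
  K <- ncol(changes)
  out <- numeric(n)
  for (g in seq_len(n)) {
    rs <- numeric(K)
    for (k in seq_len(K)) {
      x <- changes[, k]
      if (direction == "up") x <- -x
      rs[k] <- rank(x, ties.method = "average")[g]
    }
    out[g] <- prod(rs)^(1 / K)
  }
  out
}

# exact expected number of null rank products <= each observed product,
# enumerating every rank tuple in {1..n}^K (per-gene marginals are uniform
# under within-comparison permutation; linearity handles the dependence)
oracle_expected_fp <- function(n, K, obs_prod) {
  tuples <- as.matrix(expand.grid(rep(list(seq_len(n)), K)))
  prods <- apply(tuples, 1, prod)
  vapply(obs_prod, function(p) n * mean(prods <= p + 1e-9), numeric(1))
}

# upper binomial tail P(X >= k) by explicit pmf summation
oracle_binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  j <- k:n
  sum(exp(lchoose(n, j) + j * log(p) + (n - j) * log1p(-p)))
}

# PCA via eigendecomposition of the covariance matrix
oracle_pca <- function(x) {
  xc <- scale(x, center = TRUE, scale = FALSE)
  eg <- eigen(stats::cov(xc), symmetric = TRUE)
  list(values = eg$values, vectors = eg$vectors,
       variance_fraction = eg$values / sum(eg$values))
}
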