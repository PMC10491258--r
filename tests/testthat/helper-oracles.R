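# Independent oracles used across test files.

# Two-sided Fisher p by full enumeration of the hypergeometric support:
# sum the probabilities of all tables (fixed margins) no more probable than
# the observed one.
fisherEnumOracle <- function(a, b, c_, d) {
  m <- a + b           # query size
  k <- a + c_          # reference size
  n_tot <- a + b + c_ + d
  support <- max(0, m + k - n_tot):min(m, k)
  probs <- stats::dhyper(support, k, n_tot - k, m)
  p_obs <- stats::dhyper(a, k, n_tot - k, m)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Newton-Raphson IRLS for the binomial GLM, written directly from the
# likelihood: X is the design (with intercept), y successes, n trials.
newtonBinomOracle <- function(X, y, n, tol = 1e-12, maxit = 200) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    score <- drop(crossprod(X, y - n * mu))
    W <- n * mu * (1 - mu)
    info <- crossprod(X * W, X)
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

# Benjamini-Hochberg by the textbook step-up construction.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Direct eigen-count m_eff on a single window (no partitioning code shared
# with the implementation).
meffOracle <- function(G, var_explained = 0.99) {
  C <- stats::cor(t(G))
  ev <- sort(eigen(C, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev <- pmax(ev, 0)
  cum <- cumsum(ev) / sum(ev)
  which(cum >= var_explained)[1]
}

# Small deterministic genotype fixture shared across files.
smallGeno <- function(seed = 7, n_donors = 60, n_variants = 80,
                      ld_block_size = 5) {
  simulateGenotypes(simConfig(n_donors = n_donors, n_variants = n_variants,
                              ld_block_size = ld_block_size, seed = seed))
}
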