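# Fixtures and independent oracles used across the suite.

# Random phased panel with loci of intermediate frequency.
random_panel <- function(n_ind, n_loci, seed, generation = 0L) {
  set.seed(seed)
  p <- runif(n_loci, 0.2, 0.8)
  a <- matrix(rbinom(2L * n_ind * n_loci, 1L, rep(p, each = 2L * n_ind)),
              nrow = 2L * n_ind)
  haplotype_panel(a, generation = generation)
}

# Uniform single-chromosome map for a panel.
flat_map <- function(n_loci, length_cM = 100, chrom = 1L) {
  genetic_map(paste0("L", seq_len(n_loci)), rep(chrom, n_loci),
              seq(0, length_cM, length.out = n_loci))
}

# O(N^2 L) double-loop relationship oracles.
naive_G <- function(X) {
  N <- ncol(X)
  G <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    G[i, j] <- sum(X[, i] * X[, j])
  }
  G
}

naive_Q <- function(X) {
  N <- ncol(X)
  Q <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i != j) Q[i, j] <- sum((X[, i] == 0) != (X[, j] == 0))
  }
  Q
}

# Feasible random contribution vector (simplex, entries <= ub).
random_contrib <- function(n, ub = 0.5) {
  repeat {
    c0 <- rexp(n)
    c0 <- c0 / sum(c0)
    if (all(c0 <= ub)) return(c0)
  }
}

# Best sampled feasible objective value for the OCS program.
sampled_best_objective <- function(M, Y, alpha, ub = 0.5, n_samples = 1e5,
                                   seed = 1) {
  set.seed(seed)
  n <- length(Y)
  C <- matrix(rexp(n * n_samples), nrow = n)
  C <- sweep(C, 2L, colSums(C), "/")
  ok <- colSums(C > ub) == 0L
  C <- C[, ok, drop = FALSE]
  # include near-vertex candidates too
  obj <- alpha * colSums((M %*% C) * C) - (1 - alpha) * drop(crossprod(Y, C))
  min(obj)
}

# Exhaustive enumeration of integer mate plans with degree vector g
# (upper-triangle counts); returns the minimum cost.
enumerate_min_plan_cost <- function(g, cost) {
  n <- length(g)
  edges <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  best <- Inf
  rec <- function(e, rem, acc) {
    if (e > nrow(edges)) {
      if (all(rem == 0L)) best <<- min(best, acc)
      return()
    }
    i <- edges[e, 1L]; j <- edges[e, 2L]
    # prune: remaining edges must be able to absorb remaining degrees
    for (k in 0:min(rem[i], rem[j])) {
      rem[i] <- rem[i] - k; rem[j] <- rem[j] - k
      rec(e + 1L, rem, acc + k * cost[i, j])
      rem[i] <- rem[i] + k; rem[j] <- rem[j] + k
    }
  }
  rec(1L, as.integer(g), 0)
  best
}

# Sequential (type I) sums of squares by explicit successive projections.
seq_ss_oracle <- function(y, term_cols) {
  rss <- function(Xd) {
    fit <- qr.fitted(qr(Xd), y)
    sum((y - fit)^2)
  }
  Xd <- matrix(1, nrow = length(y), ncol = 1)
  out <- numeric(length(term_cols))
  prev <- rss(Xd)
  for (k in seq_along(term_cols)) {
    Xd <- cbind(Xd, term_cols[[k]])
    cur <- rss(Xd)
    out[k] <- prev - cur
    prev <- cur
  }
  out
}

# Small founder set + calibrated trait shared by pipeline-level tests.
default_founders <- function(seed = 11) {
  f <- simulate_founders(founder_spec(seed = seed))
  effects <- draw_effects(n_loci(f$panel), seed = seed + 1, panel = f$panel,
                          target_tbv_sd = 25.9)
  list(panel = f$panel, map = f$map, effects = effects)
}
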