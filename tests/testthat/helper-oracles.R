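# Independent brute-force oracles used across tests.

# TOM by the definitional triple loop.
brute_tom <- function(adj) {
  n <- nrow(adj)
  k <- rowSums(adj) - 1
  tom <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      shared <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) shared <- shared + adj[i, u] * adj[u, j]
      }
      tom[i, j] <- (shared + adj[i, j]) / (min(k[i], k[j]) + 1 - adj[i, j])
    }
  }
  dimnames(tom) <- dimnames(adj)
  tom
}

# Weighted least squares through the normal equations.
brute_wls <- function(y, x, w) {
  X <- cbind(1, x)
  XtWX <- t(X) %*% (w * X)
  beta <- solve(XtWX, t(X) %*% (w * y))
  resid <- y - X %*% beta
  df <- length(y) - 2
  list(
    beta = beta[2],
    stdev_unscaled = sqrt(solve(XtWX)[2, 2]),
    sigma2 = sum(w * resid^2) / df
  )
}

# Upper-tail hypergeometric by summing point masses.
brute_hyper_p <- function(overlap, set_size, query_size, universe_size) {
  ks <- overlap:min(set_size, query_size)
  sum(stats::dhyper(ks, set_size, universe_size - set_size, query_size))
}

# A small synthetic experiment reused by several test files.
small_sim <- function(seed = 101, n_genes = 400, n_de = 40, n_modules = 2,
                      module_size_range = c(15, 25), ...) {
  simulate_experiment(sim_params(
    n_genes = n_genes, n_de = n_de, n_modules = n_modules,
    module_size_range = module_size_range, seed = seed, ...
  ))
}
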