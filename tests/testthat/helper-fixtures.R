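# shared fixtures, all generated in code

small_panel <- function(seed = 1, noise_sd = 0.05, signal = "all",
                        n_regions = 4, n_years = 8, link = "nonlinear") {
  generate_panel(panel_config(n_regions = n_regions, n_years = n_years,
                              noise_sd = noise_sd, link = link,
                              signal = signal, seed = seed))
}

# direct dense solve of the full (n+1) x (n+1) KKT system; independent of
# the block-elimination path used by lssvm_fit()
oracle_lssvm <- function(X, y, sigma, gamma) {
  n <- nrow(X)
  K <- outer(seq_len(n), seq_len(n),
             Vectorize(function(i, j) rbf_kernel(X[i, ], X[j, ], sigma)))
  M <- rbind(c(0, rep(1, n)), cbind(1, K + diag(1 / gamma, n)))
  sol <- solve(M, c(0, y))
  list(bias = sol[1], alphas = sol[-1], K = K)
}

# brute-force weak-dominance check: is any other unit at least as good in
# every dimension and strictly better in one?
is_dominated <- function(inputs, good, bad, o) {
  n <- nrow(inputs)
  for (j in seq_len(n)[-o]) {
    leq <- all(inputs[j, ] <= inputs[o, ]) && all(bad[j, ] <= bad[o, ]) &&
      all(good[j, ] >= good[o, ])
    strict <- any(inputs[j, ] < inputs[o, ]) || any(bad[j, ] < bad[o, ]) ||
      any(good[j, ] > good[o, ])
    if (leq && strict) return(TRUE)
  }
  FALSE
}

# smooth 1-d regression toy with noise; interior loocv optimum
toy_regression <- function(n = 14, seed = 3, noise = 0.15) {
  set.seed(seed)
  x <- matrix(seq(0, 1, length.out = n))
  y <- sin(2 * pi * x[, 1]) + noise * rnorm(n)
  list(x = x, y = y)
}
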