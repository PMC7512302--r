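# Brute-force oracles, deliberately independent of the package's
# enumeration internals: states come from expand.grid and operator values
# from explicit products over index sets.

# all 2^n spin configurations as a matrix (one row per state)
oracle_states <- function(n) {
  as.matrix(do.call(expand.grid, rep(list(c(-1, 1)), n)))
}

# operator value phi_mu(s) for every state row
oracle_op_values <- function(indices, states) {
  apply(states[, indices, drop = FALSE], 1L, prod)
}

# partition function by direct summation
oracle_Z <- function(model, g) {
  states <- oracle_states(model$n)
  idx <- operator_indices(model)
  energy <- numeric(nrow(states))
  for (j in seq_along(idx))
    energy <- energy + g[j] * oracle_op_values(idx[[j]], states)
  sum(exp(energy))
}

# Fisher matrix as the covariance of operator values under P(s | g, M)
oracle_fisher <- function(model, g) {
  states <- oracle_states(model$n)
  idx <- operator_indices(model)
  vals <- vapply(idx, oracle_op_values, numeric(nrow(states)), states = states)
  energy <- as.numeric(vals %*% g)
  p <- exp(energy) / sum(exp(energy))
  mu <- colSums(p * vals)
  crossprod(vals, p * vals) - tcrossprod(mu)
}

# is `subset` a loop?  Check the defining property state by state.
oracle_is_loop <- function(model, subset) {
  if (length(subset) == 0L) return(TRUE)
  states <- oracle_states(model$n)
  idx <- operator_indices(model)[subset]
  prods <- rep(1, nrow(states))
  for (ix in idx) prods <- prods * oracle_op_values(ix, states)
  all(prods == 1)
}

# random model: m distinct operators drawn uniformly from the 2^n - 1
random_model <- function(n, m, seed) {
  masks <- spinsc:::withr_seed(seed,
    sample.int(2^n - 1L, size = m, replace = FALSE))
  spin_model(masks, n)
}

# transform a dataset to the sigma basis defined by columns of C:
# sigma_j = prod_{i : C[i,j] = 1} s_i, so that phi_m(sigma) = phi_{Cm}(s)
gauge_transform_dataset <- function(dataset, C) {
  s <- dataset$samples
  sigma <- vapply(seq_len(ncol(C)), function(j) {
    idx <- which(C[, j] == 1L)
    res <- s[, idx[1L]]
    for (i in idx[-1L]) res <- res * s[, i]
    res
  }, integer(nrow(s)))
  spin_dataset(sigma)
}

log_pi <- log(pi)
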