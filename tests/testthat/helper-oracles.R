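# Independent oracles used across the suite.

# Dense first-step analysis of the full (N+1)-state Moran chain: builds the
# complete transition matrix from the payoff definition and solves the
# absorption and conditional-mean linear systems with base linear algebra.
# Deliberately separate from the package's product-formula / phase-type code.
moran_dense_oracle <- function(N, fc, fe, s0) {
  s <- 0:N
  b <- d <- numeric(N + 1)
  for (i in 2:N) {
    si <- s[i]
    PR <- ((si - 1) / (N - 1)) * (1 - fc) + ((N - si) / (N - 1)) * fe
    tot <- si * PR + (N - si)
    b[i] <- (si * PR / tot) * (N - si) / N
    d[i] <- ((N - si) / tot) * si / N
  }
  P <- matrix(0, N + 1, N + 1)
  for (i in 1:(N + 1)) {
    P[i, i] <- 1 - b[i] - d[i]
    if (b[i] > 0) P[i, i + 1] <- b[i]
    if (d[i] > 0) P[i, i - 1] <- d[i]
  }
  tr <- 2:N
  IQ <- diag(N - 1) - P[tr, tr]
  h_ext <- solve(IQ, P[tr, 1])
  h_fix <- solve(IQ, P[tr, N + 1])
  u <- solve(IQ, h_ext)
  list(
    p_ext = h_ext[s0], p_fix = h_fix[s0],
    cond_mean_ext = u[s0] / h_ext[s0]
  )
}

# Average of the closed-form extinction time over an fe bin.
tau_bin_average <- function(lo, hi) {
  integrate(tau_approx, lo, hi, rel.tol = 1e-10)$value / (hi - lo)
}

# Branching-process oracle for the no-ecology mutant number: lineages with
# constant fitness fi ~ U(0, 1 - fc) and Poisson offspring; returns each
# lineage's integrated size after the founding generation, whose mean is
# E[fi / (1 - fi)] -- the per-(N mu) factor of the no-ecology formula plus 0.
branching_noeco_sizes <- function(n_lineages, fc, seed) {
  set.seed(seed)
  fi <- runif(n_lineages, 0, 1 - fc)
  total <- numeric(n_lineages)
  size <- rep(1, n_lineages)
  alive <- rep(TRUE, n_lineages)
  while (any(alive)) {
    size[alive] <- rpois(sum(alive), fi[alive] * size[alive])
    total[alive] <- total[alive] + size[alive]
    alive <- alive & size > 0
  }
  total
}
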