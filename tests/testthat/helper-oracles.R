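# Independent oracles and small fixture builders shared across test files.
# Everything here is deliberately naive (scalar loops, grid search,
# enumeration) so it cannot share bugs with the vectorized/compiled paths it
# checks.

# Scalar-loop log-likelihood: sum over observed entries of
# n ln p + (2 - n) ln(1 - p), p clamped as in the package.
oracle_loglik <- function(counts, Q, F_mat) {
  s <- 0
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      n <- counts[i, j]
      if (is.na(n)) next
      p <- sum(Q[i, ] * F_mat[, j])
      p <- min(max(p, 1e-10), 1 - 1e-10)
      s <- s + n * log(p) + (2 - n) * log(1 - p)
    }
  }
  s
}

# Scalar-loop penalized objective.
oracle_penalized_objective <- function(counts, Q, F_mat, lambda, gamma) {
  pen <- 0
  for (i in seq_len(nrow(Q))) {
    for (k in seq_len(ncol(Q))) {
      pen <- pen + log(1 + Q[i, k] / gamma)
    }
  }
  oracle_loglik(counts, Q, F_mat) - lambda * pen / log(1 + 1 / gamma)
}

# Exhaustive search over the 1-simplex (K = 2) for the best ancestry row of a
# single individual, at a grid resolution fine enough for the tests' use.
oracle_best_q_row <- function(counts_row, F_mat, grid_n = 2001) {
  g <- seq(0, 1, length.out = grid_n)
  vals <- vapply(g, function(q1) {
    oracle_loglik(matrix(counts_row, nrow = 1), matrix(c(q1, 1 - q1), 1, 2), F_mat)
  }, numeric(1))
  q1 <- g[which.max(vals)]
  c(q1, 1 - q1)
}

# Random valid model state and genotypes for property-style loops.
random_instance <- function(I, J, K, seed, missing_frac = 0) {
  set.seed(seed)
  Q <- matrix(rgamma(I * K, 1), I, K)
  Q <- Q / rowSums(Q)
  F_mat <- matrix(runif(K * J, 0.05, 0.95), K, J)
  P <- Q %*% F_mat
  counts <- matrix(rbinom(I * J, 2, as.vector(P)), I, J)
  if (missing_frac > 0) {
    drop_idx <- sample(I * J, ceiling(missing_frac * I * J))
    counts[drop_idx] <- NA_integer_
  }
  list(counts = counts, geno = genotype_matrix(counts), Q = Q, F = F_mat)
}

# Two well-separated populations plus optional admixed individuals; small
# scale for optimizer tests.
small_two_pop <- function(J = 600, fst = 0.2, n_ref = 30, n_admixed = 0, seed = 42) {
  simulate_dataset(simulation_design(J = J, fst = fst, n_ref_per_pop = n_ref,
                                     n_admixed = n_admixed, seed = seed))
}
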