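# Block-relaxation optimizer: initialization, block updates, acceleration,
# full fits, and their contracts.

test_that("initialization is deterministic, simplex-valid, and guards K", {
  sim <- small_two_pop(J = 100, n_ref = 10)
  s1 <- admix_init(sim$genotypes, 3, seed = 5)
  s2 <- admix_init(sim$genotypes, 3, seed = 5)
  expect_identical(s1, s2)
  expect_equal(rowSums(s1$Q), rep(1, 20), tolerance = 1e-12)
  expect_true(all(s1$F >= 1e-6 & s1$F <= 1 - 1e-6))
  # K = 1 is all ones regardless of seed
  expect_equal(admix_init(sim$genotypes, 1, seed = 1)$Q,
               admix_init(sim$genotypes, 1, seed = 999)$Q)
  expect_true(all(admix_init(sim$genotypes, 1, seed = 1)$Q == 1))
  expect_error(admix_init(sim$genotypes, 0), "at least 1")
  expect_error(admix_init(sim$genotypes, 21), "cannot exceed")
})

test_that("the Q update ascends, is a no-op at K = 1, and matches a grid-search oracle", {
  # K = 1: the simplex is a point
  sim <- small_two_pop(J = 80, n_ref = 8)
  st <- admix_init(sim$genotypes, 1, seed = 2)
  up <- update_Q_block(sim$genotypes, st$Q, st$F)
  expect_identical(up$Q, st$Q)
  # I = 1, J = 2, K = 2 with evidence all for population 1: iterated updates
  # drive q to the oracle optimum (1, 0)
  counts <- matrix(c(2L, 2L), 1, 2)
  g <- genotype_matrix(counts)
  F_mat <- matrix(c(0.9, 0.1, 0.9, 0.1), 2, 2)
  q <- matrix(c(0.5, 0.5), 1, 2)
  for (it in 1:50) q <- update_Q_block(g, q, F_mat)$Q
  oracle <- oracle_best_q_row(counts, F_mat)
  expect_equal(as.vector(q), oracle, tolerance = 1e-3)
  expect_equal(as.vector(q), c(1, 0), tolerance = 1e-3)
  # generic ascent on random instances
  for (s in 1:3) {
    inst <- random_instance(I = 7, J = 12, K = 3, seed = 200 + s)
    st0 <- admix_init(inst$geno, 3, seed = s)
    ll0 <- log_likelihood(inst$geno, st0$Q, st0$F)
    up <- update_Q_block(inst$geno, st0$Q, st0$F)
    expect_gte(up$loglik, ll0 - 1e-12)
    expect_equal(rowSums(up$Q), rep(1, 7), tolerance = 1e-9)
  }
})

test_that("the F update ascends and reaches the K = 1 empirical frequency", {
  set.seed(4)
  counts <- matrix(rbinom(40 * 25, 2, 0.35), 40, 25)
  g <- genotype_matrix(counts)
  Q <- matrix(1, 40, 1)
  F_mat <- matrix(0.5, 1, 25)
  for (it in 1:30) F_mat <- update_F_block(g, Q, F_mat)$F
  expect_equal(as.vector(F_mat), colMeans(counts) / 2, tolerance = 1e-6)
  # unadmixed individuals: each population converges to its own empirical freq
  sim <- small_two_pop(J = 60, n_ref = 20, seed = 8)
  Q2 <- sim$truth$Q_true
  F2 <- matrix(0.5, 2, 60)
  for (it in 1:40) F2 <- update_F_block(sim$genotypes, Q2, F2)$F
  cnt <- sim$genotypes$counts
  emp1 <- colMeans(cnt[1:20, ]) / 2
  emp2 <- colMeans(cnt[21:40, ]) / 2
  # empirical frequencies clipped by the frequency box
  clip <- function(x) pmin(pmax(x, 1e-6), 1 - 1e-6)
  expect_equal(as.vector(F2[1, ]), clip(emp1), tolerance = 1e-6)
  expect_equal(as.vector(F2[2, ]), clip(emp2), tolerance = 1e-6)
  # ascent property
  inst <- random_instance(I = 6, J = 9, K = 2, seed = 77)
  st <- admix_init(inst$geno, 2, seed = 1)
  ll0 <- log_likelihood(inst$geno, st$Q, st$F)
  expect_gte(update_F_block(inst$geno, st$Q, st$F)$loglik, ll0 - 1e-12)
})

test_that("quasi-Newton extrapolation accelerates without breaking ascent", {
  sim <- small_two_pop(J = 400, n_ref = 25, n_admixed = 20, seed = 12)
  plain <- admix_fit(sim$genotypes, 2, seed = 6, qn_secants = 0, max_iter = 400)
  accel <- admix_fit(sim$genotypes, 2, seed = 6, qn_secants = 3, max_iter = 400)
  expect_lte(accel$iterations, plain$iterations)
  expect_true(all(diff(accel$trajectory) >= -1e-8))
  expect_true(all(diff(plain$trajectory) >= -1e-8))
  # qn_secants = 0 path never proposes an extrapolation
  expect_null(quasi_newton_accelerate(NULL, NULL, 1:3, 2:4))
})

test_that("fitting K = 1 recovers empirical frequencies in closed form", {
  set.seed(10)
  counts <- matrix(rbinom(30 * 40, 2, runif(40)[rep(1:40, each = 30)]), 30, 40)
  g <- genotype_matrix(counts)
  fit <- admix_fit(g, 1, seed = 1, tol = 1e-8, max_iter = 300)
  clip <- function(x) pmin(pmax(x, 1e-6), 1 - 1e-6)
  expect_equal(as.vector(fit$F), clip(colMeans(counts) / 2), tolerance = 1e-6)
  expect_true(all(fit$Q == 1))
})

test_that("two well-separated populations are recovered", {
  sim <- small_two_pop(J = 3000, fst = 0.2, n_ref = 30, seed = 7)
  fit <- align_to_truth(admix_fit(sim$genotypes, 2, seed = 3), sim$truth)
  expect_lt(max(abs(fit$Q - sim$truth$Q_true)), 0.05)
  expect_true(fit$converged)
})

test_that("results are identical for any worker count", {
  sim <- small_two_pop(J = 300, n_ref = 15, n_admixed = 10, seed = 21)
  f1 <- admix_fit(sim$genotypes, 2, seed = 9, workers = 1)
  f4 <- admix_fit(sim$genotypes, 2, seed = 9, workers = 4)
  expect_identical(f1$Q, f4$Q)
  expect_identical(f1$F, f4$F)
  expect_identical(f1$trajectory, f4$trajectory)
})

test_that("seeds reaching the same objective agree up to column permutation", {
  sim <- small_two_pop(J = 800, fst = 0.2, n_ref = 25, seed = 33)
  fa <- admix_fit(sim$genotypes, 2, seed = 1)
  fb <- admix_fit(sim$genotypes, 2, seed = 2)
  expect_equal(fa$loglik, fb$loglik, tolerance = 1e-4)
  pa <- align_to_truth(fa, sim$truth)
  pb <- align_to_truth(fb, sim$truth)
  expect_equal(pa$Q, pb$Q, tolerance = 1e-2)
})

test_that("converged fits satisfy the KKT stationarity conditions", {
  sim <- small_two_pop(J = 250, n_ref = 12, n_admixed = 8, seed = 14)
  fit <- admix_fit(sim$genotypes, 2, seed = 4, tol = 1e-9, max_iter = 600)
  expect_lte(stationarity_residual(sim$genotypes, fit), 1e-4)
})

test_that("invalid optimizer configurations are rejected", {
  sim <- small_two_pop(J = 50, n_ref = 5)
  expect_error(admix_fit(sim$genotypes, 2, tol = 0), "tol")
  expect_error(admix_fit(sim$genotypes, 2, workers = 0), "workers")
  expect_error(admix_fit(sim$genotypes, 2, qn_secants = -1), "qn_secants")
  expect_error(admix_fit(sim$genotypes, 2, lambda = -1), "lambda")
})
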