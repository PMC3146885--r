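# The binomial admixture model: probabilities, likelihood, derivatives,
# deviance residuals, masking.

test_that("success probabilities are the stated convex combinations", {
  expect_equal(success_probability(matrix(1, 1, 1), matrix(0.3, 1, 1), 1, 1), 0.3)
  expect_equal(success_probability(matrix(c(0.5, 0.5), 1, 2),
                                   matrix(c(0.2, 0.8), 2, 1), 1, 1), 0.5)
  expect_equal(success_probability(matrix(c(0.25, 0.75), 1, 2),
                                   matrix(c(0.1, 0.9), 2, 1), 1, 1), 0.7)
})

test_that("predicted dosage is twice the success probability", {
  expect_equal(predicted_dosage(matrix(c(1, 0), 1, 2),
                                matrix(c(0.5, 0.9), 2, 1), 1, 1), 1.0)
  expect_equal(predicted_dosage(matrix(c(0.3, 0.7), 1, 2),
                                matrix(c(0.2, 0.6), 2, 1), 1, 1), 0.96)
  # boundary guard: frequency at its floor
  expect_equal(predicted_dosage(matrix(1, 1, 1), matrix(1e-6, 1, 1), 1, 1), 2e-6)
})

test_that("log-likelihood matches the analytic value and the scalar oracle", {
  g1 <- genotype_matrix(matrix(1L, 1, 1))
  expect_equal(log_likelihood(g1, matrix(1, 1, 1), matrix(0.5, 1, 1)),
               2 * log(0.5), tolerance = 1e-12)
  # all-missing data: empty sum
  gm <- genotype_matrix(matrix(c(0L, NA, NA, NA), 2, 2))
  masked <- mask_genotypes(gm, which(!is.na(gm$counts)))
  expect_equal(log_likelihood(masked, matrix(1, 2, 1), matrix(0.5, 1, 2)), 0)
  # random instances against the scalar loop, with and without missingness
  for (s in 1:4) {
    inst <- random_instance(I = 5 + s, J = 8 + 2 * s, K = 1 + s %% 3 + 1,
                            seed = 100 + s, missing_frac = 0.1 * (s %% 2))
    ll <- log_likelihood(inst$geno, inst$Q, inst$F)
    expect_equal(ll, oracle_loglik(inst$counts, inst$Q, inst$F),
                 tolerance = 1e-10)
  }
})

test_that("log-likelihood is invariant under population label switching", {
  inst <- random_instance(I = 8, J = 15, K = 3, seed = 17)
  perm <- c(3, 1, 2)
  expect_equal(log_likelihood(inst$geno, inst$Q[, perm], inst$F[perm, ]),
               log_likelihood(inst$geno, inst$Q, inst$F), tolerance = 1e-12)
})

test_that("block gradients match central finite differences", {
  inst <- random_instance(I = 4, J = 6, K = 3, seed = 7)
  h <- 1e-6
  qd <- block_gradients_and_hessians(inst$geno, inst$Q, inst$F, block = "Q")
  for (i in 1:4) {
    for (k in 1:3) {
      Qp <- inst$Q; Qp[i, k] <- Qp[i, k] + h
      Qm <- inst$Q; Qm[i, k] <- Qm[i, k] - h
      fd <- (oracle_loglik(inst$counts, Qp, inst$F) -
             oracle_loglik(inst$counts, Qm, inst$F)) / (2 * h)
      expect_equal(qd$gradients[i, k], fd, tolerance = 1e-5)
    }
  }
  fdv <- block_gradients_and_hessians(inst$geno, inst$Q, inst$F, block = "F")
  for (j in c(1, 4, 6)) {
    for (k in 1:3) {
      Fp <- inst$F; Fp[k, j] <- Fp[k, j] + h
      Fm <- inst$F; Fm[k, j] <- Fm[k, j] - h
      fd <- (oracle_loglik(inst$counts, inst$Q, Fp) -
             oracle_loglik(inst$counts, inst$Q, Fm)) / (2 * h)
      expect_equal(fdv$gradients[k, j], fd, tolerance = 1e-5)
    }
  }
})

test_that("block Hessians are symmetric and negative semidefinite", {
  inst <- random_instance(I = 5, J = 7, K = 3, seed = 23)
  qd <- block_gradients_and_hessians(inst$geno, inst$Q, inst$F, block = "Q")
  for (i in 1:5) {
    H <- qd$hessians[, , i]
    expect_equal(H, t(H), tolerance = 1e-12)
    expect_lte(max(eigen(H, symmetric = TRUE, only.values = TRUE)$values), 1e-8)
  }
})

test_that("gradient wrt f is positive for every population when all n = 2", {
  # with n = 2 everywhere and f below its ceiling, raising any f_kj raises L
  counts <- matrix(2L, 6, 4)
  Q <- matrix(rgamma(12, 1), 6, 2); Q <- Q / rowSums(Q)
  F_mat <- matrix(1 - 1e-3, 2, 4)
  fd <- block_gradients_and_hessians(genotype_matrix(counts), Q, F_mat, block = "F")
  expect_true(all(fd$gradients > 0))
})

test_that("the log-likelihood is concave along segments within each block", {
  inst <- random_instance(I = 6, J = 10, K = 2, seed = 31)
  set.seed(99)
  for (rep in 1:5) {
    Q2 <- matrix(rgamma(12, 1), 6, 2); Q2 <- Q2 / rowSums(Q2)
    t_grid <- seq(0, 1, length.out = 9)
    vals <- vapply(t_grid, function(t) {
      log_likelihood(inst$geno, (1 - t) * inst$Q + t * Q2, inst$F)
    }, numeric(1))
    expect_lte(max(diff(diff(vals))), 1e-9)
    F2 <- matrix(runif(20, 0.05, 0.95), 2, 10)
    vals_f <- vapply(t_grid, function(t) {
      log_likelihood(inst$geno, inst$Q, (1 - t) * inst$F + t * F2)
    }, numeric(1))
    expect_lte(max(diff(diff(vals_f))), 1e-9)
  }
})

test_that("squared deviance residuals match the closed form and its properties", {
  expect_equal(squared_deviance_residual(1, 1), 0)
  expect_equal(squared_deviance_residual(0, 1), 4 * log(2))
  expect_equal(squared_deviance_residual(2, 0.5), 4 * log(4))
  expect_error(squared_deviance_residual(1, 2), "strictly between")
  expect_error(squared_deviance_residual(3, 1), "0, 1 or 2")
  # convex in mu, minimized at mu = n
  mu_grid <- seq(0.05, 1.95, by = 0.01)
  for (n in 0:2) {
    d2 <- squared_deviance_residual(rep(n, length(mu_grid)), mu_grid)
    expect_true(all(d2 >= 0))
    expect_equal(mu_grid[which.min(d2)], ifelse(n == 0, 0.05, ifelse(n == 2, 1.95, 1)),
                 tolerance = 0.011)
    expect_gte(min(diff(diff(d2))), -1e-9) # convexity via second differences
  }
})

test_that("masking tracks the observed set and rejects bad entries", {
  counts <- matrix(c(0L, 1L, NA, 2L), 2, 2)
  g <- genotype_matrix(counts)
  expect_equal(observed_entries(g), c(1L, 2L, 4L))
  m <- mask_genotypes(g, 4L)
  expect_equal(observed_entries(m), c(1L, 2L))
  expect_true(is.na(geno_counts(m)[2, 2]))
  expect_equal(m$base$counts, counts)
  expect_error(mask_genotypes(g, 3L), "non-missing")
  expect_error(mask_genotypes(g, 99L), "out of range")
})
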