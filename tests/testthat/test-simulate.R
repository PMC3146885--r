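# Balding-Nichols simulator and the evaluation statistics.

test_that("Balding-Nichols draws satisfy the Beta moment identities", {
  # E[f | p] = p and Var[f | p] = fst * p (1 - p); check at fixed p via the
  # same Beta parameterization the simulator uses
  set.seed(123)
  n <- 10000
  fst <- 0.01
  scale <- (1 - fst) / fst
  p <- 0.3
  draws <- rbeta(n, p * scale, (1 - p) * scale)
  se_mean <- sqrt(fst * p * (1 - p) / n)
  expect_lt(abs(mean(draws) - p), 3 * se_mean)
  p2 <- 0.5
  draws2 <- rbeta(n, p2 * scale, (1 - p2) * scale)
  v <- fst * p2 * (1 - p2)
  expect_lt(abs(var(draws2) - v), 3 * v * sqrt(2 / n))
  # the simulator's own draws: pooled standardized moments across markers
  bn <- draw_balding_nichols(J = 5000, K = 2, fst = 0.05, seed = 9)
  expect_equal(dim(bn$F_true), c(2L, 5000L))
  centered <- t(bn$F_true) - bn$ancestral_freqs
  ratio <- mean(centered^2) / mean(0.05 * bn$ancestral_freqs * (1 - bn$ancestral_freqs))
  expect_lt(abs(ratio - 1), 0.1)
})

test_that("tiny fst collapses population frequencies onto the ancestral ones", {
  bn <- draw_balding_nichols(J = 2000, K = 3, fst = 1e-6, seed = 4)
  expect_lt(max(abs(t(bn$F_true) - bn$ancestral_freqs)), 0.01)
})

test_that("the cohort stacks references and an open admixture grid", {
  truth <- build_cohort(simulation_design(J = 10, n_ref_per_pop = 100,
                                          n_admixed = 200, seed = 1))
  expect_equal(dim(truth$Q_true), c(400L, 2L))
  expect_true(all(truth$Q_true[1:100, 1] == 1))
  expect_true(all(truth$Q_true[101:200, 2] == 1))
  expect_equal(truth$Q_true[201, 1], 1 / 201)
  expect_equal(truth$Q_true[400, 1], 200 / 201)
  expect_equal(rowSums(truth$Q_true), rep(1, 400))
  # no admixed individuals: all unit vectors
  t2 <- build_cohort(simulation_design(J = 10, n_ref_per_pop = 5, n_admixed = 0,
                                       seed = 1))
  expect_true(all(t2$Q_true %in% c(0, 1)))
  expect_error(simulation_design(K = 3, n_admixed = 10), "two populations")
})

test_that("genotype sampling respects the binomial model and the seed", {
  d <- simulation_design(J = 10000, K = 2, fst = 0.01, n_ref_per_pop = 1,
                         n_admixed = 0, seed = 31)
  truth <- build_cohort(d)
  truth$F_true[1, ] <- 0.5 # fix the success probability for the mean check
  g <- sample_genotypes(truth, seed = 5)
  expect_identical(g$counts, sample_genotypes(truth, seed = 5)$counts)
  # q = (1, 0), f = 0.5: mean dosage 1.0 within 3 SE
  se <- sqrt(2 * 0.5 * 0.5 / 10000)
  expect_lt(abs(mean(g$counts[1, ]) - 1.0), 3 * se)
  # f = 1 everywhere forces n = 2
  truth$F_true[] <- 1
  expect_true(all(sample_genotypes(truth, seed = 1)$counts == 2L))
})

test_that("frequency RMSE behaves as a metric on aligned matrices", {
  F_true <- matrix(runif(2 * 50), 2, 50)
  expect_equal(rmse_frequencies(F_true, F_true, 1), 0)
  expect_equal(rmse_frequencies(F_true + 0.05, F_true, 1), 0.05, tolerance = 1e-12)
  expect_error(rmse_frequencies(F_true, F_true[, 1:10]), "identical dimensions")
})

test_that("label switching is resolved by minimal-RMSE assignment", {
  F_true <- matrix(runif(2 * 100), 2, 100)
  F_hat <- F_true[c(2, 1), ] + matrix(rnorm(200, 0, 0.01), 2, 100)
  expect_equal(match_populations(F_hat, F_true), c(2L, 1L))
  fitlike <- list(Q = matrix(c(0.9, 0.1), 1, 2), F = F_hat)
  class(fitlike) <- "admix_fit"
  aligned <- align_to_truth(fitlike, list(F_true = F_true))
  expect_equal(aligned$Q[1, ], c(0.1, 0.9))
})

test_that("the FST estimator matches hand values and is consistent", {
  F_same <- matrix(runif(100), 2, 50, byrow = TRUE)
  F_same[2, ] <- F_same[1, ]
  expect_equal(estimate_fst(F_same), 0)
  # maximal divergence: the raw ratio is 2, clipped to 1
  F_max <- rbind(rep(c(0, 1), 25), rep(c(1, 0), 25))
  expect_equal(estimate_fst(F_max), 1)
  expect_error(estimate_fst(rbind(rep(0, 5), rep(0, 5))), "undefined")
  # consistency on true Balding-Nichols frequencies at large J
  bn <- draw_balding_nichols(J = 100000, K = 2, fst = 0.01, seed = 77)
  expect_lt(abs(estimate_fst(bn$F_true) - 0.01), 0.003)
})

test_that("bias curves recover the identity for perfect estimates", {
  truth <- build_cohort(simulation_design(J = 10, n_ref_per_pop = 10,
                                          n_admixed = 50, seed = 2))
  bc <- bias_curve(truth$Q_true, truth$Q_true, exclude_rows = truth$reference_rows)
  expect_equal(bc$q_hat, bc$q_true, tolerance = 1e-12)
  expect_error(bias_curve(truth$Q_true[1:25, ], truth$Q_true[1:25, ],
                          exclude_rows = 1:20), "fewer than 10")
  # loess flavor runs and returns finite values
  bl <- bias_curve(truth$Q_true, truth$Q_true,
                   exclude_rows = truth$reference_rows, method = "loess")
  expect_true(all(is.finite(bl$q_hat)))
})

test_that("simulations round-trip through the truth sidecar files", {
  sim <- simulate_dataset(simulation_design(J = 40, n_ref_per_pop = 6,
                                            n_admixed = 10, seed = 8))
  tmp <- tempfile()
  write_simulation(sim, tmp)
  expect_true(all(file.exists(paste0(tmp, c(".bed", ".bim", ".fam", ".ind",
                                            ".truth.Q", ".truth.P", ".truth.meta")))))
  back <- read_plink_bed(paste0(tmp, ".bed"))
  expect_identical(back$counts, sim$genotypes$counts)
  qback <- as.matrix(read.table(paste0(tmp, ".truth.Q")))
  dimnames(qback) <- NULL
  expect_equal(qback, sim$truth$Q_true, tolerance = 1e-5)
})
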