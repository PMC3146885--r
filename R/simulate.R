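# Balding-Nichols simulation of admixed cohorts, plus the evaluation
# statistics used to judge fits against the simulation truth: frequency RMSE,
# a Wright-style FST estimate, and ancestry bias curves.

#' Describe a simulation design
#'
#' The default design is the two-population benchmark used throughout the
#' package: 10,000 markers, F_ST = 0.01 (closely related populations within a
#' continent), 100 reference individuals from each population and 200 admixed
#' individuals on a uniform ancestry grid.
#'
#' @param J number of markers.
#' @param K number of ancestral populations.
#' @param fst Balding-Nichols differentiation, in `(0, 1)`.
#' @param n_ref_per_pop reference (unadmixed) individuals per population.
#' @param n_admixed grid-admixed individuals (requires `K = 2` when positive).
#' @param seed integer seed.
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(J = 10000L, K = 2L, fst = 0.01,
                              n_ref_per_pop = 100L, n_admixed = 200L,
                              seed = 1L) {
  if (fst <= 0 || fst >= 1) stop("fst must lie strictly between 0 and 1")
  if (J < 1L || K < 1L) stop("J and K must be at least 1")
  if (n_ref_per_pop < 0L || n_admixed < 0L) stop("cohort counts must be nonnegative")
  if (n_admixed > 0L && K != 2L) {
    stop("the admixture grid is defined between two populations; use K = 2 or n_admixed = 0")
  }
  structure(list(J = as.integer(J), K = as.integer(K), fst = fst,
                 n_ref_per_pop = as.integer(n_ref_per_pop),
                 n_admixed = as.integer(n_admixed), seed = as.integer(seed)),
            class = "simulation_design")
}

#' Draw Balding-Nichols allele frequencies
#'
#' Ancestral frequencies `p_j ~ Uniform(0, 1)`; per-population frequencies
#' `f_kj ~ Beta(p_j (1 - fst) / fst, (1 - p_j)(1 - fst) / fst)`, independent
#' across populations and markers, so that `E[f_kj] = p_j` and
#' `Var[f_kj] = fst * p_j (1 - p_j)`.
#'
#' @param J number of markers.
#' @param K number of populations.
#' @param fst differentiation, in `(0, 1)`.
#' @param seed integer seed.
#' @return List with `ancestral_freqs` (length J) and `F_true` (K x J).
#' @export
draw_balding_nichols <- function(J, K, fst, seed = 1L) {
  if (fst <= 0 || fst >= 1) stop("fst must lie strictly between 0 and 1")
  with_seed(seed, {
    p <- runif(J)
    scale <- (1 - fst) / fst
    F_true <- t(vapply(seq_len(K),
                       function(k) rbeta(J, p * scale, (1 - p) * scale),
                       numeric(J)))
    list(ancestral_freqs = p, F_true = F_true)
  })
}

#' Build the cohort's true ancestry matrix and frequencies
#'
#' Stacks `n_ref_per_pop` unit-vector rows per population followed by
#' `n_admixed` rows whose population-1 fraction runs over the open uniform
#' grid `i / (n_admixed + 1)`, `i = 1..n_admixed` (endpoints excluded: those
#' are the reference designs).
#'
#' @param design a [simulation_design()].
#' @return An object of class `simulation_truth`: `ancestral_freqs`, `F_true`,
#'   `Q_true`, `design`, and `reference_rows` (indices of the unadmixed
#'   individuals).
#' @export
build_cohort <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  bn <- draw_balding_nichols(design$J, design$K, design$fst, seed = design$seed)
  Qrows <- list()
  for (k in seq_len(design$K)) {
    if (design$n_ref_per_pop > 0L) {
      u <- matrix(0, design$n_ref_per_pop, design$K)
      u[, k] <- 1
      Qrows[[length(Qrows) + 1L]] <- u
    }
  }
  if (design$n_admixed > 0L) {
    g <- seq_len(design$n_admixed) / (design$n_admixed + 1)
    Qrows[[length(Qrows) + 1L]] <- cbind(g, 1 - g)
  }
  Q_true <- do.call(rbind, Qrows)
  dimnames(Q_true) <- NULL
  if (is.null(Q_true) || nrow(Q_true) < 1L) stop("design yields an empty cohort")
  structure(list(ancestral_freqs = bn$ancestral_freqs,
                 F_true = bn$F_true,
                 Q_true = Q_true,
                 design = design,
                 reference_rows = seq_len(design$K * design$n_ref_per_pop)),
            class = "simulation_truth")
}

#' Sample genotypes from a simulation truth
#'
#' Each `n_ij ~ Binomial(2, sum_k q_ik f_kj)` independently; no missingness.
#'
#' @param truth a [build_cohort()] object.
#' @param seed integer seed.
#' @return A [genotype_matrix()].
#' @export
sample_genotypes <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "simulation_truth"))
  P <- truth$Q_true %*% truth$F_true
  I <- nrow(P)
  J <- ncol(P)
  counts <- with_seed(seed, {
    matrix(rbinom(I * J, size = 2L, prob = as.vector(P)), I, J)
  })
  genotype_matrix(counts)
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: builds the cohort from the design seed, samples
#' genotypes from a derived seed, and attaches reference population labels
#' (`POP1`, `POP2`, ... for the unadmixed individuals, unlabeled for the
#' admixed ones).
#'
#' @param design a [simulation_design()].
#' @return List with `genotypes`, `truth` and `labels`.
#' @export
simulate_dataset <- function(design) {
  truth <- build_cohort(design)
  genotypes <- sample_genotypes(truth, seed = derive_seed(design$seed, 1L))
  assignments <- rep(NA_character_, nrow(truth$Q_true))
  if (design$n_ref_per_pop > 0L) {
    assignments[truth$reference_rows] <-
      rep(paste0("POP", seq_len(design$K)), each = design$n_ref_per_pop)
  }
  labels <- if (any(!is.na(assignments))) {
    population_labels(assignments, paste0("POP", seq_len(design$K)))
  } else NULL
  list(genotypes = genotypes, truth = truth, labels = labels)
}

#' Write a simulated dataset with its truth sidecar
#'
#' Emits the PLINK fileset through [write_plink_bed()], the reference labels
#' as `.ind`, and a plain-text sidecar (`prefix.truth.Q`, `prefix.truth.P`,
#' `prefix.truth.meta`) holding the generating `Q`, `F`, ancestral
#' frequencies, F_ST and seed, so downstream stages are testable without
#' regeneration.
#'
#' @param sim a [simulate_dataset()] result.
#' @param path_prefix output prefix.
#' @return `path_prefix`, invisibly.
#' @export
write_simulation <- function(sim, path_prefix) {
  write_plink_bed(sim$genotypes, path_prefix)
  if (!is.null(sim$labels)) write_ind_file(sim$labels, paste0(path_prefix, ".ind"))
  write.table(format(sim$truth$Q_true, digits = 6, scientific = FALSE, trim = TRUE),
              paste0(path_prefix, ".truth.Q"), quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(format(t(sim$truth$F_true), digits = 6, scientific = FALSE, trim = TRUE),
              paste0(path_prefix, ".truth.P"), quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  d <- sim$truth$design
  writeLines(c(sprintf("J %d", d$J), sprintf("K %d", d$K),
               sprintf("fst %g", d$fst),
               sprintf("n_ref_per_pop %d", d$n_ref_per_pop),
               sprintf("n_admixed %d", d$n_admixed),
               sprintf("seed %d", d$seed),
               paste("ancestral_freqs",
                     paste(format(sim$truth$ancestral_freqs, digits = 6,
                                  scientific = FALSE, trim = TRUE),
                           collapse = " "))),
             paste0(path_prefix, ".truth.meta"))
  invisible(path_prefix)
}

# ---------------------------------------------------------------------------
# Evaluation statistics
# ---------------------------------------------------------------------------

#' Match estimated populations to true populations
#'
#' The likelihood is invariant under permutation of population labels, so
#' estimated populations must be aligned to the truth before any error
#' statistic is meaningful. Returns the permutation (estimated index for each
#' true index) minimizing the total frequency RMSE; exhaustive over
#' permutations (K is small).
#'
#' @param F_hat,F_true K x J frequency matrices.
#' @return Integer vector `perm` such that `F_hat[perm[k], ]` estimates
#'   `F_true[k, ]`.
#' @export
match_populations <- function(F_hat, F_true) {
  K <- nrow(F_true)
  if (nrow(F_hat) != K || ncol(F_hat) != ncol(F_true)) {
    stop("F_hat and F_true must have identical dimensions")
  }
  if (K > 8L) stop("exhaustive label matching supports K <= 8")
  cost <- outer(seq_len(K), seq_len(K),
                Vectorize(function(a, b) sqrt(mean((F_hat[a, ] - F_true[b, ])^2))))
  perms <- all_permutations(K)
  totals <- vapply(perms, function(p) sum(cost[cbind(p, seq_len(K))]), numeric(1))
  perms[[which.min(totals)]]
}

all_permutations <- function(K) {
  if (K == 1L) return(list(1L))
  sub <- all_permutations(K - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(K)) {
      out[[length(out) + 1L]] <- append(p, K, after = pos - 1L)
    }
  }
  out
}

#' Align a fit to the simulation truth
#'
#' Applies the [match_populations()] permutation to the columns of `Q` and
#' rows of `F` of a fit so that population `k` of the fit corresponds to
#' population `k` of the truth.
#'
#' @param fit an `admix_fit` object.
#' @param truth a `simulation_truth`.
#' @return The fit with permuted `Q` columns and `F` rows.
#' @export
align_to_truth <- function(fit, truth) {
  perm <- match_populations(fit$F, truth$F_true)
  fit$Q <- fit$Q[, perm, drop = FALSE]
  fit$F <- fit$F[perm, , drop = FALSE]
  fit
}

#' Root-mean-squared error of an estimated frequency vector
#'
#' `sqrt(mean((f_hat_pop - f_true_pop)^2))` over markers, for one population.
#' Assumes label switching has already been resolved (see
#' [align_to_truth()]).
#'
#' @param F_hat,F_true K x J frequency matrices, aligned.
#' @param pop population (row) index.
#' @return The RMSE.
#' @export
rmse_frequencies <- function(F_hat, F_true, pop = 1L) {
  if (!all(dim(F_hat) == dim(F_true))) stop("F_hat and F_true must have identical dimensions")
  sqrt(mean((F_hat[pop, ] - F_true[pop, ])^2))
}

#' Wright-style F_ST estimate from two frequency vectors
#'
#' Ratio-of-averages estimator between two populations:
#' `sum_j (f_1j - f_2j)^2 / 2` divided by `sum_j pbar_j (1 - pbar_j)` with
#' `pbar_j = (f_1j + f_2j) / 2`. Consistent for the Balding-Nichols
#' differentiation when applied to the true frequencies; estimation error in
#' the frequencies inflates it. The raw ratio can exceed 1 for maximally
#' divergent fixed frequencies, so the report is clipped to `[0, 1]`.
#'
#' @param F_hat 2 x J matrix of allele frequencies.
#' @return The estimated F_ST in `[0, 1]`.
#' @export
estimate_fst <- function(F_hat) {
  if (nrow(F_hat) != 2L) stop("estimate_fst expects exactly two populations (2 x J matrix)")
  pbar <- colMeans(F_hat)
  den <- sum(pbar * (1 - pbar))
  if (den <= 0) stop("F_ST undefined: every averaged frequency is fixed at 0 or 1")
  num <- sum((F_hat[1L, ] - F_hat[2L, ])^2) / 2
  min(max(num / den, 0), 1)
}

#' Ancestry bias curve
#'
#' Smoothed conditional mean of the estimated population-1 ancestry fraction
#' given the true fraction, over the admixed individuals. Reference
#' individuals are excluded by default (their rows are fixed or trivially
#' recovered and would flatten the curve). The binned smoother (20 equal-width
#' bins, default) is deterministic; `method = "loess"` fits a local
#' regression with the given span instead.
#'
#' @param Q_hat,Q_true I x K ancestry matrices, label-switching resolved.
#' @param exclude_rows row indices to drop (typically the reference
#'   individuals).
#' @param method `"bins"` or `"loess"`.
#' @param bins number of bins for the binned smoother.
#' @param span loess span.
#' @return Data frame with columns `q_true` (bin mean or grid of true
#'   fractions) and `q_hat` (smoothed estimate).
#' @export
bias_curve <- function(Q_hat, Q_true, exclude_rows = NULL,
                       method = c("bins", "loess"), bins = 20L, span = 0.5) {
  method <- match.arg(method)
  if (!all(dim(Q_hat) == dim(Q_true))) stop("Q_hat and Q_true must have identical dimensions")
  q_true <- Q_true[, 1L]
  q_hat <- Q_hat[, 1L]
  if (length(exclude_rows)) {
    q_true <- q_true[-exclude_rows]
    q_hat <- q_hat[-exclude_rows]
  }
  if (length(q_true) < 10L) stop("fewer than 10 admixed individuals: refusing to smooth")
  if (method == "bins") {
    bin <- pmin(pmax(ceiling(q_true * bins), 1L), bins)
    keep <- sort(unique(bin))
    data.frame(q_true = vapply(keep, function(b) mean(q_true[bin == b]), numeric(1)),
               q_hat = vapply(keep, function(b) mean(q_hat[bin == b]), numeric(1)))
  } else {
    fit <- loess(q_hat ~ q_true, span = span,
                 data = data.frame(q_true = q_true, q_hat = q_hat))
    grid <- seq(min(q_true), max(q_true), length.out = 101L)
    data.frame(q_true = grid, q_hat = as.vector(predict(fit, newdata = data.frame(q_true = grid))))
  }
}

#' Mean absolute ancestry bias
#'
#' Mean over (non-reference) individuals of `|q_hat_i1 - q_true_i1|`; the
#' scalar summary used to compare penalized with unpenalized fits.
#'
#' @inheritParams bias_curve
#' @return The mean absolute error of the population-1 ancestry fraction.
#' @export
mean_abs_q_bias <- function(Q_hat, Q_true, exclude_rows = NULL) {
  if (!all(dim(Q_hat) == dim(Q_true))) stop("Q_hat and Q_true must have identical dimensions")
  d <- abs(Q_hat[, 1L] - Q_true[, 1L])
  if (length(exclude_rows)) d <- d[-exclude_rows]
  mean(d)
}
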