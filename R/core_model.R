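# The binomial admixture model: success probabilities, log-likelihood,
# analytic block derivatives, predicted dosages, deviance residuals, and
# entry masking.

# Boundary guards shared with the C++ core. Allele frequencies live in
# [EPS_F, 1-EPS_F]; binomial probabilities are clamped to [P_CLAMP, 1-P_CLAMP]
# before logs so the likelihood stays finite.
EPS_F <- 1e-6
P_CLAMP <- 1e-10

clamp_prob <- function(p) pmin(pmax(p, P_CLAMP), 1 - P_CLAMP)

validate_state <- function(Q, F_mat) {
  Q <- as.matrix(Q)
  F_mat <- as.matrix(F_mat)
  if (ncol(Q) != nrow(F_mat)) stop("Q and F disagree on the number of populations K")
  if (any(Q < 0)) stop("ancestry fractions must be nonnegative")
  if (any(abs(rowSums(Q) - 1) > 1e-8)) stop("each row of Q must sum to 1")
  if (any(F_mat < 0) || any(F_mat > 1)) stop("allele frequencies must lie in [0, 1]")
  invisible(TRUE)
}

#' Binomial success probability of the admixture model
#'
#' `p_ij = sum_k q_ik f_kj`: the convex combination of row `i` of `Q` with
#' column `j` of `F`, i.e. the modeled frequency of the counted allele in
#' individual `i` at marker `j`.
#'
#' @param Q I x K row-stochastic ancestry matrix.
#' @param F_mat K x J allele-frequency matrix.
#' @param i,j individual and marker index.
#' @return A probability in `[0, 1]`.
#' @export
success_probability <- function(Q, F_mat, i, j) {
  validate_state(Q, F_mat)
  drop(Q[i, , drop = FALSE] %*% F_mat[, j, drop = FALSE])
}

#' Predicted genotype dosage
#'
#' The model's conditional mean genotype `mu_ij = 2 p_ij`, used to predict
#' masked entries in cross-validation.
#'
#' @inheritParams success_probability
#' @return A real number in `[0, 2]`.
#' @export
predicted_dosage <- function(Q, F_mat, i, j) {
  2 * success_probability(Q, F_mat, i, j)
}

#' Log-likelihood of the admixture model
#'
#' `L(Q, F) = sum_(i,j observed) n_ij ln p_ij + (2 - n_ij) ln(1 - p_ij)` with
#' `p_ij = sum_k q_ik f_kj`. Missing and masked entries are excluded from the
#' sum; probabilities are clamped away from \{0, 1\} before the logs.
#'
#' @param genotypes a [genotype_matrix()], [mask_genotypes()] object, or bare
#'   integer matrix.
#' @inheritParams success_probability
#' @return A finite real number (0 when every entry is missing).
#' @export
log_likelihood <- function(genotypes, Q, F_mat) {
  validate_state(Q, F_mat)
  counts <- geno_counts(genotypes)
  cpp_loglik(counts, as.matrix(Q), as.matrix(F_mat))
}

#' Per-block gradients and Hessians of the log-likelihood
#'
#' With `F` fixed the log-likelihood separates over individuals; with `Q`
#' fixed, over markers. For `block = "Q"` returns, per individual, the
#' K-gradient and K x K (negative semidefinite) Hessian with respect to that
#' individual's ancestry row; for `block = "F"`, the per-marker equivalents
#' with respect to the marker's frequency column. Only observed entries
#' contribute.
#'
#' @inheritParams log_likelihood
#' @param block `"Q"` or `"F"`.
#' @return A list with `gradients` (I x K or K x J matrix) and `hessians`
#'   (K x K x I or K x K x J array).
#' @export
block_gradients_and_hessians <- function(genotypes, Q, F_mat, block = c("Q", "F")) {
  block <- match.arg(block)
  validate_state(Q, F_mat)
  counts <- geno_counts(genotypes)
  if (block == "Q") {
    cpp_q_derivs(t(counts), as.matrix(Q), as.matrix(F_mat))
  } else {
    cpp_f_derivs(counts, as.matrix(Q), as.matrix(F_mat))
  }
}

#' Squared binomial deviance residual
#'
#' For a genotype `n` in \{0, 1, 2\} and predicted dosage `mu` in `(0, 2)`:
#' `d^2(n, mu) = 2 [ n ln(n/mu) + (2-n) ln((2-n)/(2-mu)) ]` with the
#' convention `0 ln 0 = 0`. Nonnegative, zero iff `n == mu`. Vectorized.
#'
#' @param n observed genotype count(s) in \{0, 1, 2\}.
#' @param mu predicted dosage(s) in the open interval `(0, 2)`.
#' @return Squared deviance residual(s).
#' @export
squared_deviance_residual <- function(n, mu) {
  if (any(is.na(n)) || any(!n %in% c(0, 1, 2))) stop("n must be 0, 1 or 2")
  if (any(mu <= 0) || any(mu >= 2)) stop("mu must lie strictly between 0 and 2")
  t1 <- ifelse(n == 0, 0, n * log(n / mu))
  t2 <- ifelse(n == 2, 0, (2 - n) * log((2 - n) / (2 - mu)))
  pmax(2 * (t1 + t2), 0)
}

#' Mask genotype entries
#'
#' Marks a set of observed entries as temporarily missing, as done for one
#' cross-validation fold. The base matrix is retained so that masked truths
#' remain available for scoring predictions.
#'
#' @param genotypes a [genotype_matrix()].
#' @param entries linear indices into the count matrix, or a 2-column
#'   (row, col) index matrix. All must address non-missing entries.
#' @return An object of class `masked_genotypes` with fields `base`,
#'   `masked_set` (sorted linear indices) and `counts` (the masked matrix).
#' @export
mask_genotypes <- function(genotypes, entries) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  counts <- genotypes$counts
  if (is.matrix(entries) && ncol(entries) == 2L) {
    entries <- entries[, 1L] + (entries[, 2L] - 1L) * nrow(counts)
  }
  entries <- sort(unique(as.integer(entries)))
  if (length(entries) && (min(entries) < 1L || max(entries) > length(counts))) {
    stop("masked entry index out of range")
  }
  if (any(is.na(counts[entries]))) {
    stop("masked entries must address non-missing genotypes")
  }
  masked <- counts
  masked[entries] <- NA_integer_
  structure(list(base = genotypes, masked_set = entries, counts = masked),
            class = "masked_genotypes")
}

#' @export
print.masked_genotypes <- function(x, ...) {
  cat(sprintf("masked_genotypes: %d x %d, %d entries masked (of %d observed)\n",
              nrow(x$counts), ncol(x$counts), length(x$masked_set),
              sum(!is.na(x$base$counts))))
  invisible(x)
}

#' Observed entry indices
#'
#' Linear indices of entries that are non-missing (and, for masked objects,
#' not masked).
#'
#' @param genotypes a `genotype_matrix` or `masked_genotypes` object.
#' @return Integer vector of linear indices.
#' @export
observed_entries <- function(genotypes) {
  which(!is.na(geno_counts(genotypes)))
}
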