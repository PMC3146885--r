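# Approximate-l0 penalized estimation: the penalty, the penalized objective,
# and the penalized Q update (a thin wrapper: the optimizer core handles the
# penalty whenever lambda > 0).

#' Approximate-\eqn{\ell_0} penalty on ancestry coefficients
#'
#' `pen(Q) = lambda * sum_(i,k) ln(1 + q_ik / gamma) / ln(1 + 1 / gamma)`.
#' The normalization makes a coefficient of 1 cost exactly `lambda` and a
#' coefficient of 0 cost nothing; as `gamma -> 0` the penalty tends to
#' `lambda` times the number of nonzero entries, which is why it encourages
#' not just shrinkage but exact zeros (parsimony). Applied to `Q` only, never
#' to the allele frequencies.
#'
#' @param Q I x K ancestry matrix (row-stochastic).
#' @param lambda penalty strength, `>= 0`.
#' @param gamma penalty scale, `> 0`.
#' @param exclude_rows optional row indices excluded from the penalty
#'   (supervised reference individuals: their rows are constants).
#' @return The penalty value, `>= 0`.
#' @export
penalty_value <- function(Q, lambda, gamma, exclude_rows = NULL) {
  if (lambda < 0) stop("lambda must be nonnegative")
  if (lambda == 0) return(0)
  if (gamma <= 0) stop("gamma must be positive")
  Q <- as.matrix(Q)
  if (length(exclude_rows)) Q <- Q[-exclude_rows, , drop = FALSE]
  if (nrow(Q) == 0L) return(0)
  lambda * sum(log1p(Q / gamma)) / log1p(1 / gamma)
}

#' Penalized objective
#'
#' The log-likelihood minus the approximate-\eqn{\ell_0} penalty; the quantity
#' the optimizer maximizes (and whose monotone ascent it guarantees) in
#' penalized mode. With `lambda = 0` it equals the log-likelihood exactly.
#'
#' @inheritParams log_likelihood
#' @inheritParams penalty_value
#' @return A real number.
#' @export
penalized_objective <- function(genotypes, Q, F_mat, lambda, gamma = 0.1,
                                exclude_rows = NULL) {
  log_likelihood(genotypes, Q, F_mat) -
    penalty_value(Q, lambda, gamma, exclude_rows = exclude_rows)
}

#' Penalized SQP pass over the ancestry rows
#'
#' Identical contract to [update_Q_block()] with the penalty active: the QP
#' uses the likelihood's quadratic model plus a local linear approximation of
#' the concave penalty (a true minorization, so the safeguarded acceptance
#' against the exact penalized row objective preserves monotone ascent), and
#' entries driven to the boundary become exact zeros. With `lambda = 0` the
#' step reduces to the plain update.
#'
#' @inheritParams update_Q_block
#' @return List with the updated `Q` and `loglik`.
#' @export
penalized_update_Q_block <- function(genotypes, Q, F_mat, lambda, gamma = 0.1,
                                     fixed_rows = NULL, workers = 1L) {
  update_Q_block(genotypes, Q, F_mat, fixed_rows = fixed_rows,
                 lambda = lambda, gamma = gamma, workers = workers)
}
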