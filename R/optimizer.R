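# Block-relaxation optimizer: alternating SQP updates of Q and F with
# safeguarded quasi-Newton extrapolation of the block-update map.

#' Initialize the model state
#'
#' Ancestry rows are drawn from a flat Dirichlet; allele frequencies start at
#' the overall empirical frequency of each marker perturbed by uniform noise
#' (so that populations are not initialized identically), clamped to
#' `[1e-6, 1 - 1e-6]`. With `fixed_rows`, the constrained rows are set to
#' exact unit vectors. Fully deterministic given `seed`.
#'
#' @param genotypes a [genotype_matrix()] or masked equivalent.
#' @param K number of ancestral populations (`1 <= K <= I`).
#' @param seed integer seed.
#' @param fixed_rows optional data frame with columns `individual` and
#'   `column`, as built by [build_constraints()].
#' @return List with elements `Q` (I x K), `F` (K x J) and `K`.
#' @export
admix_init <- function(genotypes, K, seed = 1L, fixed_rows = NULL) {
  counts <- geno_counts(genotypes)
  I <- nrow(counts)
  J <- ncol(counts)
  K <- as.integer(K)
  if (K < 1L) stop("K must be at least 1")
  if (K > I) stop("K cannot exceed the number of individuals")
  state <- with_seed(seed, {
    Q <- matrix(rgamma(I * K, shape = 1), I, K)
    Q <- Q / rowSums(Q)
    pbar <- colMeans(counts, na.rm = TRUE) / 2
    pbar[!is.finite(pbar)] <- 0.5
    F_mat <- matrix(rep(pbar, each = K), K, J) + matrix(runif(K * J, -0.1, 0.1), K, J)
    list(Q = Q, F = pmin(pmax(F_mat, EPS_F), 1 - EPS_F))
  })
  if (!is.null(fixed_rows) && nrow(fixed_rows) > 0L) {
    for (r in seq_len(nrow(fixed_rows))) {
      i <- fixed_rows$individual[r]
      state$Q[i, ] <- 0
      state$Q[i, fixed_rows$column[r]] <- 1
    }
  }
  list(Q = state$Q, F = state$F, K = K)
}

#' One SQP pass over the ancestry rows
#'
#' For each non-fixed individual independently, solves the quadratic program
#' maximizing the second-order Taylor expansion of the (optionally penalized)
#' log-likelihood in that row, subject to the probability-simplex constraints,
#' then step-halves toward the current point until the true row objective does
#' not decrease. Fixed rows are returned unchanged.
#'
#' @inheritParams admix_init
#' @param Q,F_mat current state.
#' @param lambda,gamma approximate-\eqn{\ell_0} penalty constants
#'   (`lambda = 0` disables the penalty).
#' @param workers number of threads for the independent row subproblems;
#'   results are identical for any value.
#' @return List with the updated `Q` and `loglik` (log-likelihood at the new
#'   state, penalty not included).
#' @export
update_Q_block <- function(genotypes, Q, F_mat, fixed_rows = NULL,
                           lambda = 0, gamma = 0.1, workers = 1L) {
  counts <- geno_counts(genotypes)
  fixed <- logical(nrow(counts))
  if (!is.null(fixed_rows) && nrow(fixed_rows) > 0L) fixed[fixed_rows$individual] <- TRUE
  res <- cpp_update_Q(t(counts), as.matrix(Q), as.matrix(F_mat), fixed,
                      lambda, gamma, as.integer(workers))
  if (res$n_failed > 0L) {
    warning(res$n_failed, " ancestry row subproblem(s) fell back to a no-op")
  }
  list(Q = res$Q, loglik = res$loglik)
}

#' One SQP pass over the allele-frequency columns
#'
#' For each marker independently, a safeguarded QP step on the K-vector of
#' frequencies subject to the box constraints `[1e-6, 1 - 1e-6]`. The penalty
#' never touches `F`, so this update is identical in plain and penalized mode.
#'
#' @inheritParams update_Q_block
#' @return List with the updated `F` and `loglik` at the new state.
#' @export
update_F_block <- function(genotypes, Q, F_mat, workers = 1L) {
  counts <- geno_counts(genotypes)
  res <- cpp_update_F(counts, as.matrix(Q), as.matrix(F_mat), as.integer(workers))
  if (res$n_failed > 0L) {
    warning(res$n_failed, " frequency column subproblem(s) fell back to a no-op")
  }
  list(F = res$F, loglik = res$loglik)
}

# Flatten / unflatten the (Q, F) state for the quasi-Newton extrapolation.
flatten_state <- function(Q, F_mat) c(as.vector(Q), as.vector(F_mat))
unflatten_state <- function(x, I, K, J) {
  list(Q = matrix(x[seq_len(I * K)], I, K),
       F = matrix(x[I * K + seq_len(K * J)], K, J))
}

#' Quasi-Newton extrapolation of the block-update map
#'
#' Secant-based acceleration of the fixed-point iteration `x -> M(x)` defined
#' by one full block-relaxation sweep: with `U` the last few differences of
#' iterates and `V` the matching differences of their images,
#' `x_acc = M(x) + V (U'U - U'V)^(-1) U' (M(x) - x)`. Returns `NULL` when the
#' secant system is singular; the caller then keeps the plain step. The caller
#' must project the proposal to the feasible set and accept it only if it
#' improves the objective, which preserves monotone ascent regardless of the
#' extrapolation's quality.
#'
#' @param U,V matrices whose columns are the recent secant differences.
#' @param x current flattened state.
#' @param mx flattened state after one plain block sweep from `x`.
#' @return The extrapolated flattened state, or `NULL`.
#' @export
quasi_newton_accelerate <- function(U, V, x, mx) {
  if (is.null(U) || ncol(U) == 0L) return(NULL)
  C <- crossprod(U) - crossprod(U, V)
  d <- mx - x
  sol <- tryCatch(solve(C, crossprod(U, d)), error = function(e) NULL)
  if (is.null(sol) || any(!is.finite(sol))) return(NULL)
  as.vector(mx + V %*% sol)
}

# Project a proposed state back to the feasible set: simplex rows (clamp at 0,
# renormalize), frequency box, and exact unit vectors for fixed rows.
project_state <- function(Q, F_mat, fixed_rows = NULL) {
  Q[Q < 0] <- 0
  rs <- rowSums(Q)
  if (any(rs <= 0)) return(NULL)
  Q <- Q / rs
  if (!is.null(fixed_rows) && nrow(fixed_rows) > 0L) {
    for (r in seq_len(nrow(fixed_rows))) {
      i <- fixed_rows$individual[r]
      Q[i, ] <- 0
      Q[i, fixed_rows$column[r]] <- 1
    }
  }
  F_mat <- pmin(pmax(F_mat, EPS_F), 1 - EPS_F)
  list(Q = Q, F = F_mat)
}

#' Fit the admixture model
#'
#' Maximizes the log-likelihood (minus the approximate-\eqn{\ell_0} penalty
#' when `lambda > 0`) by block relaxation: alternating SQP updates of `Q` and
#' `F`, accelerated by safeguarded quasi-Newton extrapolation. Every accepted
#' step increases the objective, so the trajectory is non-decreasing. The
#' result is identical for any `workers` count.
#'
#' @inheritParams admix_init
#' @param lambda,gamma penalty constants; `lambda = 0` (default) fits plain
#'   maximum likelihood. Fixed (reference) rows are excluded from the penalty.
#' @param tol convergence threshold on the objective increase between
#'   consecutive (accelerated) iterations.
#' @param max_iter iteration cap.
#' @param qn_secants number of secant differences retained for the
#'   extrapolation; `0` disables acceleration.
#' @param workers thread count for the independent subproblems.
#' @param init optional starting state (as from [admix_init()]); default draws
#'   one from `seed`.
#' @param verbose print the objective each iteration.
#' @return An object of class `admix_fit`: `Q`, `F`, `K`, `loglik` (final
#'   log-likelihood), `objective` (equals `loglik` minus the penalty),
#'   `trajectory` (objective after each iteration), `iterations`, `converged`,
#'   plus the call's tuning constants.
#' @export
admix_fit <- function(genotypes, K, lambda = 0, gamma = 0.1, fixed_rows = NULL,
                      seed = 1L, tol = 1e-4, max_iter = 200L, qn_secants = 3L,
                      workers = 1L, init = NULL, verbose = FALSE) {
  if (tol <= 0) stop("tol must be positive")
  if (qn_secants < 0L) stop("qn_secants must be nonnegative")
  if (workers < 1L) stop("workers must be at least 1")
  if (lambda < 0) stop("lambda must be nonnegative")
  if (lambda > 0 && gamma <= 0) stop("gamma must be positive")
  counts <- geno_counts(genotypes)
  I <- nrow(counts)
  J <- ncol(counts)
  K <- as.integer(K)
  state <- init %||% admix_init(genotypes, K, seed = seed, fixed_rows = fixed_rows)
  Q <- state$Q
  F_mat <- state$F
  countsT <- t(counts)
  fixed <- logical(I)
  if (!is.null(fixed_rows) && nrow(fixed_rows) > 0L) fixed[fixed_rows$individual] <- TRUE

  pen <- function(Q) penalty_value(Q, lambda, gamma, exclude_rows = which(fixed))
  objective <- function(Q, F_mat, ll = NULL) {
    (ll %||% cpp_loglik(counts, Q, F_mat)) - pen(Q)
  }

  # one full block sweep (Q then F), returning the new state and objective
  block_sweep <- function(Q, F_mat) {
    rq <- cpp_update_Q(countsT, Q, F_mat, fixed, lambda, gamma, as.integer(workers))
    rf <- cpp_update_F(counts, rq$Q, F_mat, as.integer(workers))
    list(Q = rq$Q, F = rf$F, loglik = rf$loglik,
         obj = rf$loglik - pen(rq$Q))
  }

  obj <- objective(Q, F_mat)
  if (!is.finite(obj)) stop("non-finite objective at initialization")
  trajectory <- numeric(0)
  U <- V <- NULL
  prev_x <- prev_mx <- NULL
  converged <- FALSE
  iterations <- 0L
  final_ll <- NULL

  for (it in seq_len(max_iter)) {
    sweep <- block_sweep(Q, F_mat)
    if (!is.finite(sweep$obj)) stop("non-finite objective during optimization")
    x <- flatten_state(Q, F_mat)
    mx <- flatten_state(sweep$Q, sweep$F)
    if (!is.null(prev_x)) {
      U <- cbind(U, x - prev_x)
      V <- cbind(V, mx - prev_mx)
      if (ncol(U) > qn_secants) {
        U <- U[, -1L, drop = FALSE]
        V <- V[, -1L, drop = FALSE]
      }
    }
    next_Q <- sweep$Q
    next_F <- sweep$F
    next_obj <- sweep$obj
    next_ll <- sweep$loglik
    if (qn_secants > 0L && !is.null(U) && ncol(U) == qn_secants) {
      xa <- quasi_newton_accelerate(U, V, x, mx)
      if (!is.null(xa)) {
        cand <- unflatten_state(xa, I, K, J)
        cand <- project_state(cand$Q, cand$F, fixed_rows)
        if (!is.null(cand)) {
          cll <- cpp_loglik(counts, cand$Q, cand$F)
          cobj <- cll - pen(cand$Q)
          if (is.finite(cobj) && cobj > next_obj) {
            next_Q <- cand$Q
            next_F <- cand$F
            next_obj <- cobj
            next_ll <- cll
          }
        }
      }
    }
    prev_x <- x
    prev_mx <- mx
    delta <- next_obj - obj
    Q <- next_Q
    F_mat <- next_F
    obj <- next_obj
    final_ll <- next_ll
    trajectory <- c(trajectory, obj)
    iterations <- it
    if (verbose) {
      message(sprintf("iter %3d: objective %.6f (delta %.3e)", it, obj, delta))
    }
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }

  structure(
    list(Q = Q, F = F_mat, K = K,
         loglik = final_ll %||% cpp_loglik(counts, Q, F_mat),
         objective = obj,
         trajectory = trajectory,
         iterations = iterations,
         converged = converged,
         lambda = lambda, gamma = gamma,
         fixed_rows = fixed_rows, seed = seed),
    class = "admix_fit"
  )
}

#' @export
print.admix_fit <- function(x, ...) {
  cat(sprintf("admix_fit: K = %d, %d individuals x %d markers\n",
              x$K, nrow(x$Q), ncol(x$F)))
  cat(sprintf("  log-likelihood %.4f%s after %d iteration(s)%s\n",
              x$loglik,
              if (x$lambda > 0) sprintf(" (objective %.4f, lambda = %g, gamma = %g)",
                                        x$objective, x$lambda, x$gamma) else "",
              x$iterations,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' KKT stationarity residual of a fitted state
#'
#' Largest violation of the first-order optimality conditions over all
#' ancestry rows (simplex constraints) and frequency columns (box
#' constraints), for the objective the fit maximized (penalty included when
#' `lambda > 0`, penalized rows only). At an exact constrained maximum the
#' residual is 0.
#'
#' @param genotypes the data the model was fitted to.
#' @param fit an `admix_fit` object.
#' @return The maximum projected-gradient residual (infinity norm).
#' @export
stationarity_residual <- function(genotypes, fit) {
  counts <- geno_counts(genotypes)
  Q <- fit$Q
  F_mat <- fit$F
  K <- fit$K
  fixed <- logical(nrow(Q))
  if (!is.null(fit$fixed_rows) && nrow(fit$fixed_rows) > 0L) {
    fixed[fit$fixed_rows$individual] <- TRUE
  }
  qd <- cpp_q_derivs(t(counts), Q, F_mat)
  worst <- 0
  lnorm <- if (fit$lambda > 0) log1p(1 / fit$gamma) else 1
  for (i in seq_len(nrow(Q))) {
    if (fixed[i]) next
    g <- qd$gradients[i, ]
    if (fit$lambda > 0) g <- g - fit$lambda / ((Q[i, ] + fit$gamma) * lnorm)
    free <- Q[i, ] > 1e-12
    if (!any(free)) next
    nu <- mean(g[free])
    resid <- max(abs(g[free] - nu), if (any(!free)) pmax(0, g[!free] - nu) else 0)
    worst <- max(worst, resid)
  }
  fd <- cpp_f_derivs(counts, Q, F_mat)
  at_lo <- F_mat <= EPS_F + 1e-12
  at_hi <- F_mat >= 1 - EPS_F - 1e-12
  g <- fd$gradients
  resid_f <- abs(g)
  resid_f[at_lo] <- pmax(0, g[at_lo])
  resid_f[at_hi] <- pmax(0, -g[at_hi])
  max(worst, max(resid_f))
}
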