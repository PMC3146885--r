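# v-fold entry-masking cross-validation: fold construction, prediction-error
# estimation by squared binomial deviance residuals, and grid selection of K
# or of the penalty strength lambda.

#' Partition observed genotype entries into folds
#'
#' Uniformly random balanced partition of the non-missing entries (individual
#' cells, not individuals or markers) into `v` folds, reproducible from
#' `seed`. Fold sizes differ by at most one.
#'
#' @param genotypes a [genotype_matrix()].
#' @param v number of folds, `>= 2`.
#' @param seed integer seed.
#' @return An object of class `fold_assignment` with fields `v`, `entries`
#'   (linear indices of observed entries), `fold` (fold index per entry) and
#'   `seed`.
#' @export
make_folds <- function(genotypes, v, seed = 1L) {
  v <- as.integer(v)
  if (v < 2L) stop("v must be at least 2")
  obs <- observed_entries(genotypes)
  n <- length(obs)
  if (v > n) stop(sprintf("v = %d exceeds the number of observed entries (%d)", v, n))
  fold <- integer(n)
  with_seed(seed, {
    fold[sample.int(n)] <- rep(seq_len(v), length.out = n)
  })
  structure(list(v = v, entries = obs, fold = fold, seed = seed),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("fold_assignment: %d observed entries in %d folds (sizes %s)\n",
              length(x$entries), x$v,
              paste(tabulate(x$fold, x$v), collapse = ", ")))
  invisible(x)
}

#' Cross-validation prediction error
#'
#' For each fold: masks its entries, refits the model on the masked data,
#' predicts each masked genotype by its fitted dosage `mu_ij = 2 sum_k q_ik
#' f_kj`, and scores it with the squared binomial deviance residual. Returns
#' the mean over all masked entries across all folds. Each fold's fit is
#' re-initialized with a deterministic seed derived from the master seed and
#' the fold's entry set (so the error is invariant to how folds are labeled).
#' Dosages at a clamp boundary are nudged inside `(0, 2)` to keep the
#' residual finite.
#'
#' @param genotypes a [genotype_matrix()].
#' @param K number of populations for the fits.
#' @param folds a [make_folds()] assignment.
#' @param lambda,gamma penalty constants for penalized fits (`lambda = 0` for
#'   plain maximum likelihood).
#' @param fixed_rows optional supervised constraints, passed to [admix_fit()].
#' @param ... further arguments passed to [admix_fit()] (`tol`, `max_iter`,
#'   `workers`, ...).
#' @return Mean squared deviance residual over masked entries.
#' @export
cv_error <- function(genotypes, K, folds, lambda = 0, gamma = 0.1,
                     fixed_rows = NULL, ...) {
  stopifnot(inherits(folds, "fold_assignment"))
  counts <- geno_counts(genotypes)
  I <- nrow(counts)
  total <- 0
  n_entries <- 0L
  for (f in seq_len(folds$v)) {
    idx <- folds$entries[folds$fold == f]
    if (!length(idx)) next
    masked <- mask_genotypes(genotypes, idx)
    mc <- masked$counts
    row_gone <- setdiff(which(rowSums(!is.na(counts)) > 0), which(rowSums(!is.na(mc)) > 0))
    col_gone <- setdiff(which(colSums(!is.na(counts)) > 0), which(colSums(!is.na(mc)) > 0))
    if (length(row_gone) || length(col_gone)) {
      warning(sprintf("fold %d masks every observed entry of %d individual(s)/%d marker(s); their parameters are unidentifiable", f, length(row_gone), length(col_gone)))
    }
    fit <- admix_fit(masked, K, lambda = lambda, gamma = gamma,
                     fixed_rows = fixed_rows,
                     seed = derive_seed(folds$seed, sum(as.numeric(idx))), ...)
    ij <- arrayInd(idx, dim(counts))
    mu <- 2 * rowSums(fit$Q[ij[, 1L], , drop = FALSE] * t(fit$F)[ij[, 2L], , drop = FALSE])
    mu <- pmin(pmax(mu, 2 * P_CLAMP), 2 - 2 * P_CLAMP)
    total <- total + sum(squared_deviance_residual(counts[idx], mu))
    n_entries <- n_entries + length(idx)
  }
  total / n_entries
}

cv_result <- function(grid, errors, what) {
  ok <- is.finite(errors)
  if (!any(ok)) stop("every grid point failed; no ", what, " can be selected")
  selected <- grid[ok][which.min(errors[ok])]
  structure(list(grid = grid, errors = errors, selected = selected, what = what),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cross-validation over %s:\n", x$what))
  for (i in seq_along(x$grid)) {
    cat(sprintf("  %s = %-8g CV error = %s%s\n", x$what, x$grid[i],
                formatC(x$errors[i], digits = 6, format = "f"),
                if (x$grid[i] == x$selected) "  <- selected" else ""))
  }
  invisible(x)
}

#' Format a cross-validation table
#'
#' One row per grid value with its estimated prediction error, as written by
#' the command-line interface.
#'
#' @param x a `cv_result`.
#' @return A data frame with columns named after the tuned constant and
#'   `cv_error`.
#' @export
cv_table <- function(x) {
  stopifnot(inherits(x, "cv_result"))
  out <- data.frame(x$grid, x$errors)
  names(out) <- c(x$what, "cv_error")
  out
}

#' Select the number of ancestral populations by cross-validation
#'
#' Runs [cv_error()] for each value of `K_grid` on a single fold assignment
#' and returns the grid, the per-K errors, and the minimizing `K` (ties broken
#' toward the smaller value). A grid point whose fits fail is recorded as `NA`
#' rather than aborting the grid.
#'
#' @param genotypes a [genotype_matrix()].
#' @param K_grid ascending vector of candidate `K` values.
#' @param v number of folds (default 5).
#' @param seed master seed for fold assignment and fold fits.
#' @param ... further arguments passed to [cv_error()].
#' @return A `cv_result` object.
#' @export
select_K <- function(genotypes, K_grid, v = 5L, seed = 1L, ...) {
  if (!length(K_grid)) stop("K_grid must be nonempty")
  if (is.unsorted(K_grid, strictly = TRUE)) stop("K_grid must be strictly ascending")
  folds <- make_folds(genotypes, v, seed = seed)
  errors <- vapply(K_grid, function(K) {
    tryCatch(cv_error(genotypes, K, folds, ...),
             error = function(e) {
               warning(sprintf("K = %d failed: %s", K, conditionMessage(e)))
               NA_real_
             })
  }, numeric(1))
  cv_result(K_grid, errors, "K")
}

#' Select the penalty strength by cross-validation
#'
#' Runs penalized cross-validation for each `lambda` on a fixed `gamma` and a
#' single fold assignment; returns the minimizing `lambda`, ties toward the
#' smaller value.
#'
#' @inheritParams select_K
#' @param K number of populations of the penalized fits.
#' @param lambda_grid candidate penalty strengths (nonnegative).
#' @param gamma penalty scale, `> 0`.
#' @return A `cv_result` object.
#' @export
select_lambda <- function(genotypes, K, lambda_grid, gamma = 0.1, v = 5L,
                          seed = 1L, ...) {
  if (!length(lambda_grid)) stop("lambda_grid must be nonempty")
  if (gamma <= 0) stop("gamma must be positive")
  lambda_grid <- sort(lambda_grid)
  folds <- make_folds(genotypes, v, seed = seed)
  errors <- vapply(lambda_grid, function(lam) {
    tryCatch(cv_error(genotypes, K, folds, lambda = lam, gamma = gamma, ...),
             error = function(e) {
               warning(sprintf("lambda = %g failed: %s", lam, conditionMessage(e)))
               NA_real_
             })
  }, numeric(1))
  cv_result(lambda_grid, errors, "lambda")
}
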