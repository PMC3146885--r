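# Supervised estimation: reference individuals' ancestry rows fixed to their
# labeled population's unit vector.

#' Build fixed-row constraints from population labels
#'
#' Maps each labeled individual to the unit vector of its population's column.
#' The population-to-column order is the order of `labels$population_names`,
#' so column `k` of the fitted `Q`/`F` corresponds to the `k`-th named
#' population. Unlabeled individuals are unconstrained.
#'
#' @param labels a [population_labels()] object.
#' @param K number of populations of the fit; must equal the number of named
#'   populations.
#' @return A data frame with columns `individual` (row index) and `column`
#'   (population column index), suitable for the `fixed_rows` argument of
#'   [admix_fit()].
#' @export
build_constraints <- function(labels, K) {
  stopifnot(inherits(labels, "population_labels"))
  if (length(labels$population_names) != K) {
    stop(sprintf("supervised mode requires K (%d) to equal the number of labeled populations (%d)",
                 K, length(labels$population_names)))
  }
  labeled <- which(!is.na(labels$assignments))
  data.frame(individual = labeled,
             column = match(labels$assignments[labeled], labels$population_names))
}

#' Supervised admixture fit
#'
#' Fits the model with every labeled (reference) individual's ancestry row
#' fixed to its population's unit vector; only unlabeled individuals' rows and
#' all allele frequencies are estimated. With fewer free parameters and no
#' uncertainty in the reference ancestries, allele frequencies — and hence the
#' ancestry of the unlabeled individuals — are typically estimated more
#' precisely than in the unsupervised fit of the same data. `K` is the number
#' of labeled populations. Fixed rows are exact unit vectors in the output
#' and, in penalized runs, are excluded from the penalty.
#'
#' @param genotypes a [genotype_matrix()].
#' @param labels a [population_labels()] object aligned with the individuals.
#' @param ... further arguments passed to [admix_fit()] (`lambda`, `seed`,
#'   `tol`, ...).
#' @return An `admix_fit` object.
#' @export
supervised_fit <- function(genotypes, labels, ...) {
  K <- length(labels$population_names)
  fixed <- build_constraints(labels, K)
  admix_fit(genotypes, K, fixed_rows = fixed, ...)
}
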