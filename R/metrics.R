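#' Scalar mean dispersion error of replicated coefficient estimates
#'
#' Monte-Carlo estimate of `E[(beta - beta_hat)'(beta - beta_hat)]`, the
#' trace of the MSE matrix of the coefficient estimator: the average squared
#' Euclidean distance between each replicate's estimate and the truth. It
#' decomposes (empirically, exactly) as `tr(Var) + ||bias||^2`.
#'
#' @param beta_hats Matrix or data frame of replicate estimates, one row per
#'   replicate, one column per coefficient.
#' @param beta_true True coefficient vector.
#' @return Nonnegative scalar.
#' @examples
#' smde(rbind(c(2, -0.5), c(0, -0.5)), c(1, -0.5))  # 1
#' @export
smde <- function(beta_hats, beta_true) {
  B <- as.matrix(beta_hats)
  stopifnot(ncol(B) == length(beta_true), nrow(B) >= 1)
  E <- sweep(B, 2, beta_true)
  mean(rowSums(E^2))
}

#' Relative efficiency of two estimators
#'
#' The ratio `SMDE(estimator 1) / SMDE(estimator 2)`; a value below 1 means
#' estimator 1 is the more efficient.
#'
#' @param smde_num,smde_den SMDE of the two estimators (denominator `> 0`).
#' @return Scalar ratio.
#' @export
relative_efficiency <- function(smde_num, smde_den) {
  if (smde_den <= 0) abort("denominator SMDE must be positive")
  smde_num / smde_den
}

#' Relative-efficiency matrix over several methods
#'
#' Entry `(row = A, col = B)` is `SMDE(B) / SMDE(A)`: the column method's
#' SMDE in the numerator, so entries below 1 in row A flag column methods
#' more efficient than A. The diagonal is 1 and the matrix is antisymmetric
#' under inversion: `RE[A, B] * RE[B, A] = 1`.
#'
#' @param smdes Named vector of SMDE values, one per method.
#' @return Square matrix with method names on both dimensions.
#' @export
re_matrix <- function(smdes) {
  stopifnot(!is.null(names(smdes)), all(smdes > 0))
  outer(smdes, smdes, function(a, b) b / a)
}

#' Root mean squared error of one estimated component function
#'
#' `sqrt(mean((f_true - f_hat)^2))` over the evaluation points. Both vectors
#' should be on the same (mean-centred) scale: additive components are
#' identifiable only up to constants, so the truth must be centred the same
#' way the estimates are.
#'
#' @param f_true,f_hat Numeric vectors of equal length.
#' @return Nonnegative scalar.
#' @export
rmse_function <- function(f_true, f_hat) {
  if (length(f_true) != length(f_hat)) {
    abort("`f_true` and `f_hat` must have equal length")
  }
  sqrt(mean((f_true - f_hat)^2))
}

#' Averaged RMSE over the additive components
#'
#' Arithmetic mean of the per-function RMSE values, summarising the accuracy
#' of the whole additive part.
#'
#' @param rmses Numeric vector of per-function RMSE values (length `q >= 1`).
#' @return Scalar mean.
#' @export
armse <- function(rmses) {
  stopifnot(length(rmses) >= 1)
  mean(rmses)
}
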