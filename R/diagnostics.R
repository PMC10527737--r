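#' Error-variance estimate from a hat matrix
#'
#' \deqn{\hat\sigma^2_\varepsilon =
#'   \frac{Z'(I-H)'(I-H)Z}{\mathrm{tr}\{(I-H)'(I-H)\}},}
#' the residual sum of squares of the working response over the residual
#' degrees of freedom of [degrees_of_freedom()].
#'
#' @param z Working response vector.
#' @param H Hat matrix of the fit.
#' @return Nonnegative scalar estimate of the error variance.
#' @export
estimate_variance <- function(z, H) {
  stopifnot(length(z) == nrow(H), nrow(H) == ncol(H))
  df <- degrees_of_freedom(H)
  if (df <= 0) abort("residual degrees of freedom are not positive")
  r <- z - drop(H %*% z)
  sum(r^2) / df
}

#' Conditional bias of the parametric coefficients
#'
#' Evaluates the finite-sample conditional bias formula of the non-iterative
#' estimator,
#' \deqn{B(\hat\beta) = (X'W\tilde X)^{-1} X'W \tilde f, \qquad
#'   \tilde f = \sum_j (I - S_{h_j}) f_j,}
#' with identity weights for the ST and kNNI solutions and the Kaplan-Meier
#' weight diagonal for KMW. Requires the true component functions, so it is a
#' simulation diagnostic. Affine true components give (numerically) zero bias
#' because local linear smoothers reproduce affine functions.
#'
#' @param fit A `plam` fit carrying the additive smoother (fit with
#'   `compute_hat = TRUE`).
#' @param f_true Matrix (`n x q`) of true component values at the observed
#'   nonparametric covariates.
#' @return Named numeric vector of biases, one per parametric coefficient.
#' @export
beta_bias <- function(fit, f_true) {
  stopifnot(inherits(fit, "plam"))
  if (is.null(fit$S_add)) abort("fit lacks the additive smoother; refit with compute_hat = TRUE")
  f_true <- as.matrix(f_true)
  n <- nrow(fit$data)
  q <- length(fit$smoothers)
  if (nrow(f_true) != n || ncol(f_true) != q) {
    abort(paste0("`f_true` must be ", n, " x ", q))
  }
  ft <- rowSums(vapply(seq_len(q), function(j) {
    fj <- f_true[, j]
    fj - drop(fit$smoothers[[j]] %*% fj)
  }, numeric(n)))
  Xd <- cbind(`(Intercept)` = rep(1, n), cd_X(fit$data))
  ww <- if (is.null(fit$weights)) rep(1, n) else fit$weights
  Xt <- Xd - fit$S_add %*% Xd
  M <- crossprod(Xd, ww * Xt)
  b <- drop(solve(M, crossprod(Xd, ww * ft)))
  stats::setNames(b[-1], cd_roles(fit$data)$parametric)
}

#' Sandwich covariance of the parametric coefficients
#'
#' \deqn{\mathrm{Var}(\hat\beta) = \hat\sigma^2_\varepsilon
#'   (X'W\tilde X)^{-1} X'W (I-S^A)(I-S^A)' W X (X'W\tilde X)^{-T}},
#' the covariance of the linear coefficient functional of the non-iterative
#' estimator, using the fit's error-variance estimate. With no smoothing and
#' identity weights this reduces to the OLS covariance
#' `sigma^2 (X'X)^{-1}`.
#'
#' @param fit A `plam` fit carrying the additive smoother and `sigma2`.
#' @return Symmetric positive semidefinite `p x p` matrix (parametric
#'   coefficients, intercept excluded).
#' @export
beta_variance <- function(fit) {
  stopifnot(inherits(fit, "plam"))
  if (is.null(fit$S_add)) abort("fit lacks the additive smoother; refit with compute_hat = TRUE")
  n <- nrow(fit$data)
  Xd <- cbind(`(Intercept)` = rep(1, n), cd_X(fit$data))
  ww <- if (is.null(fit$weights)) rep(1, n) else fit$weights
  ImS <- diag(n) - fit$S_add
  Xt <- ImS %*% Xd
  M <- crossprod(Xd, ww * Xt)
  A <- solve(M, crossprod(Xd, ww * ImS))   # beta_hat = A z
  V <- fit$sigma2 * A %*% t(A)
  asym <- max(abs(V - t(V)))
  if (asym > 1e-8 * max(1, max(abs(V)))) {
    abort("coefficient covariance is asymmetric beyond tolerance")
  }
  V <- (V + t(V)) / 2
  idx <- seq_len(ncol(Xd))[-1]
  out <- V[idx, idx, drop = FALSE]
  dimnames(out) <- rep(list(cd_roles(fit$data)$parametric), 2)
  out
}
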