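kernel_fun <- function(kernel) {
  switch(kernel,
         gaussian = stats::dnorm,
         epanechnikov = function(u) 0.75 * pmax(1 - u^2, 0),
         abort(paste0("unknown kernel: ", kernel)))
}

#' Diagonal kernel weight matrix at one evaluation point
#'
#' Returns `diag(h^-1 K((t_i - m)/h))`, the weights entering the local linear
#' system at evaluation point `m`. The kernel must be a symmetric density
#' with finite second moment; the Gaussian (default) and Epanechnikov kernels
#' are provided.
#'
#' @param t Numeric covariate vector.
#' @param m Evaluation point.
#' @param h Bandwidth, in covariate units, `> 0`.
#' @param kernel `"gaussian"` or `"epanechnikov"`.
#' @return An `n x n` diagonal matrix of nonnegative weights.
#' @export
kernel_weight_matrix <- function(t, m, h, kernel = "gaussian") {
  stopifnot(h > 0)
  K <- kernel_fun(kernel)
  w <- K((t - m) / h) / h
  if (all(w == 0)) {
    abort(paste0("all kernel weights underflow to 0 at evaluation point m = ",
                 format(m), "; bandwidth h = ", format(h), " is far too small"))
  }
  diag(w, nrow = length(w))
}

#' Local linear regression smoother matrix
#'
#' Builds the `n x n` smoother `S` whose row `m` carries the local linear
#' weights at the observed point `t_m`:
#' `s_m' = d1' (T_m' W_m T_m)^-1 T_m' W_m` with `d1 = (1, 0)'`,
#' `T_m = [1, t - t_m]` and `W_m` the kernel weight diagonal of
#' [kernel_weight_matrix()]. Every row sums to 1 and `S` reproduces affine
#' functions of `t` exactly: `S (a + b t) = a + b t`.
#'
#' Near-singular 2x2 local systems (all kernel mass on one point) fall back
#' to a small ridge on the local Gram matrix, with a one-time warning.
#'
#' For the Kaplan-Meier-weighted solution, per-observation weights can be
#' folded into the local systems via `obs_weights`: the kernel weight of
#' observation `i` is multiplied by `w_i`, so the components solve the same
#' weighted least-squares objective as the coefficients (zero-weight censored
#' rows do not pull the smooth). Uniform weights leave the smoother
#' unchanged.
#'
#' @inheritParams kernel_weight_matrix
#' @param ridge Ridge added to the local 2x2 system when it is numerically
#'   singular.
#' @param obs_weights Optional nonnegative per-observation weights folded
#'   into the kernel weights.
#' @return An `n x n` matrix with attributes `h`, `kernel`,
#'   `centered = FALSE`.
#' @seealso [center_smoother()], [hat_matrix()]
#' @export
llr_smoother <- function(t, h, kernel = "gaussian", ridge = 1e-8,
                         obs_weights = NULL) {
  stopifnot(h > 0)
  if (length(unique(t)) < 2) abort("need at least 2 distinct covariate values")
  n <- length(t)
  K <- kernel_fun(kernel)
  D <- outer(t, t, function(ti, tm) ti - tm)   # D[m, i] wanted: build transposed
  # D as computed: D[a, b] = t[a] - t[b]; row m needs t_i - t_m = D[i, m] = -D[m, i]
  U <- -D                                       # U[m, i] = t[i] - t[m]
  Kw <- K(U / h) / h
  if (!is.null(obs_weights)) {
    stopifnot(length(obs_weights) == n, all(obs_weights >= 0))
    Kw <- sweep(Kw, 2, obs_weights, `*`)
  }
  zero_rows <- rowSums(Kw) == 0
  if (any(zero_rows)) {
    abort(paste0("all kernel weights underflow to 0 at evaluation point(s) t = ",
                 paste(format(t[zero_rows]), collapse = ", "),
                 "; increase the bandwidth"))
  }
  s0 <- rowSums(Kw)
  s1 <- rowSums(Kw * U)
  s2 <- rowSums(Kw * U^2)
  det <- s0 * s2 - s1^2
  bad <- det <= 1e-12 * pmax(s0 * s2, .Machine$double.xmin)
  if (any(bad)) {
    warn("near-singular local linear system; adding ridge to the local Gram matrix")
    det[bad] <- (s0[bad] + ridge) * (s2[bad] + ridge) - s1[bad]^2
    s0[bad] <- s0[bad] + ridge
  }
  S <- Kw * (s2 - U * s1) / det
  structure(S, h = h, kernel = kernel, centered = FALSE)
}

#' Mean-centre a smoother matrix
#'
#' Applies the projection `(I - n^-1 1 1') S`, so that the fitted component
#' `S v` has mean zero for any input `v`. Additive components are
#' identifiable only up to constants (absorbed by the intercept), so every
#' component smoother used in the fit is centred this way. Centring an
#' already-centred smoother is a no-op.
#'
#' @param S A smoother matrix from [llr_smoother()].
#' @return The centred matrix, with `centered = TRUE`.
#' @export
center_smoother <- function(S) {
  if (isTRUE(attr(S, "centered"))) return(S)
  Sc <- sweep(S, 2, colMeans(S))
  attributes(Sc) <- attributes(S)
  attr(Sc, "centered") <- TRUE
  Sc
}

#' Hat matrix of the partially linear fit for a given smoother
#'
#' For smoother `S`, parametric design `X` and optional observation weights
#' `w` (Kaplan-Meier weights for the weighted solution, identity otherwise),
#' returns
#' \deqn{H = S + \tilde X (X' W \tilde X)^{-1} X' W (I - S), \qquad
#'       \tilde X = (I - S) X,}
#' the linear operator mapping the working response to the fitted values of
#' the partially linear (weighted) least-squares + smoothing fit. With no
#' parametric part `H = S`; with `S = 0` it reduces to the (weighted)
#' parametric projection.
#'
#' @param S An `n x n` smoother matrix (use the centred smoother, or the sum
#'   of per-component operators for the additive fit).
#' @param X Parametric design matrix (`n x p`), may be `NULL` or 0-column.
#' @param w Optional nonnegative weight vector of length `n`.
#' @return An `n x n` matrix.
#' @export
hat_matrix <- function(S, X = NULL, w = NULL) {
  n <- nrow(S)
  if (is.null(X) || NCOL(X) == 0) return(S)
  X <- as.matrix(X)
  if (is.null(w)) w <- rep(1, n)
  Xt <- X - S %*% X
  M <- crossprod(X, w * Xt)
  Minv <- tryCatch(solve(M), error = function(e) {
    abort("singular parametric cross-product X'W(I-S)X; check for collinear or unscaled covariates")
  })
  ImS <- diag(n) - S
  S + Xt %*% Minv %*% crossprod(X, w * ImS)
}

#' Residual degrees of freedom of a linear smoother
#'
#' Computes `tr((I - H)'(I - H)) = n - 2 tr(H) + tr(H'H)`, the residual
#' degrees of freedom used in the error-variance estimate and the GCV score.
#'
#' @param H A square hat matrix.
#' @return A nonnegative scalar.
#' @export
degrees_of_freedom <- function(H) {
  stopifnot(nrow(H) == ncol(H))
  nrow(H) - 2 * sum(diag(H)) + sum(H * H)
}

#' Generalized cross-validation score
#'
#' `GCV(h) = RSS / (n (1 - tr(H)/n)^2)` for fitted values `mu_hat = H z`.
#' Candidates with `tr(H) >= n` receive an infinite score (rejected, not an
#' error).
#'
#' @param z Working response vector.
#' @param mu_hat Fitted values.
#' @param H The hat matrix that produced `mu_hat` (or its trace as a scalar
#'   via `trace_H`).
#' @param trace_H Optional precomputed `tr(H)`; `H` may then be omitted.
#' @return A scalar score.
#' @export
gcv_score <- function(z, mu_hat, H = NULL, trace_H = NULL) {
  n <- length(z)
  if (is.null(trace_H)) trace_H <- sum(diag(H))
  if (trace_H >= n) return(Inf)
  sum((z - mu_hat)^2) / (n * (1 - trace_H / n)^2)
}

# GCV for one bandwidth without materialising the full hat matrix.
# Observation weights (KMW) enter both the smoother and the parametric block.
# Returns Inf for rejected candidates: singular cross-product, tr >= n, or
# tr(H) > 0.9 n (near-interpolating fits make the GCV denominator collapse
# and stall backfitting; at least 10% residual df is required).
gcv_fast <- function(t, h, z, X, w, kernel, ridge) {
  S <- center_smoother(llr_smoother(t, h, kernel = kernel, ridge = ridge,
                                    obs_weights = w))
  n <- length(z)
  Sz <- drop(S %*% z)
  trS <- sum(diag(S))
  if (is.null(X) || NCOL(X) == 0) {
    if (trS > 0.9 * n) return(Inf)
    return(gcv_score(z, Sz, trace_H = trS))
  }
  ww <- if (is.null(w)) rep(1, n) else w
  SX <- S %*% X
  Xt <- X - SX
  M <- crossprod(X, ww * Xt)
  Minv <- tryCatch(solve(M), error = function(e) NULL)
  if (is.null(Minv)) return(Inf)
  # correction term C = Xt Minv X'W(I - S); need tr(C) and C z
  B <- crossprod(X, ww * (Xt - S %*% Xt))    # X'W(I-S)Xt
  trH <- trS + sum(diag(Minv %*% B))
  if (trH > 0.9 * n) return(Inf)
  mu <- Sz + drop(Xt %*% (Minv %*% crossprod(X, ww * (z - Sz))))
  gcv_score(z, mu, trace_H = trH)
}

#' Select a local linear bandwidth by GCV
#'
#' Evaluates the GCV score over a grid of candidate bandwidths for one
#' nonparametric component, using the method-appropriate hat matrix of
#' [hat_matrix()] (weights enter for the Kaplan-Meier-weighted solution), and
#' returns the grid minimiser. Ties go to the smaller bandwidth.
#'
#' The default grid spans `[0.01, 1.5]` multiplied by the sample range of the
#' covariate (so the nominal endpoints apply to a range-1 covariate), with
#' `grid_len` equally spaced points.
#'
#' @param t Nonparametric covariate vector.
#' @param z Working response (or current partial residual).
#' @param X Parametric design matrix including any intercept column, or
#'   `NULL`.
#' @param w Optional observation weights.
#' @param grid Optional explicit bandwidth grid (ascending).
#' @param control A [plam_control()] list (kernel, grid and ridge settings).
#' @return A `bandwidth_search` object: list with `grid`, `scores`, and
#'   `chosen` (the argmin bandwidth).
#' @export
select_bandwidth <- function(t, z, X = NULL, w = NULL, grid = NULL,
                             control = plam_control()) {
  if (is.null(grid)) {
    scale <- diff(range(t))
    if (scale == 0) abort("degenerate covariate: zero range")
    grid <- seq(control$grid_min, control$grid_max,
                length.out = control$grid_len) * scale
  }
  scores <- vapply(grid, function(h)
    gcv_fast(t, h, z, X, w, control$kernel, control$ridge), numeric(1))
  if (!any(is.finite(scores))) {
    abort("no bandwidth candidate produced a finite GCV score; extend the grid")
  }
  chosen <- grid[which.min(scores)]
  structure(list(grid = grid, scores = scores, chosen = chosen),
            class = "bandwidth_search")
}

#' @export
print.bandwidth_search <- function(x, ...) {
  cat(sprintf("<bandwidth_search> %d candidates in [%.4g, %.4g], chosen h = %.4g\n",
              length(x$grid), min(x$grid), max(x$grid), x$chosen))
  invisible(x)
}

#' @export
tidy.bandwidth_search <- function(x, ...) {
  tibble(h = x$grid, gcv = x$scores, chosen = x$grid == x$chosen)
}
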