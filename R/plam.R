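#' Control parameters for censored PLAM fitting
#'
#' @param kernel Kernel for the local linear smoothers (`"gaussian"`, the
#'   default, or `"epanechnikov"`).
#' @param grid_min,grid_max,grid_len Bandwidth search grid: `grid_len` equally
#'   spaced candidates spanning `[grid_min, grid_max]` times the sample range
#'   of each nonparametric covariate.
#' @param ridge Ridge added to near-singular local 2x2 systems in
#'   [llr_smoother()].
#' @param tol Backfitting convergence tolerance: iteration stops when the
#'   mean absolute change of the fitted component values drops below `tol`.
#' @param max_iter Maximum backfitting sweeps.
#' @param reselect_bandwidths If `TRUE`, bandwidths are re-selected by GCV at
#'   every sweep; by default they are selected once on the first sweep and
#'   frozen.
#' @param compute_hat If `TRUE` (default), the additive smoother, overall hat
#'   matrix, error variance and residual degrees of freedom are computed
#'   after convergence (requires solving an `nq x nq` linear system; disable
#'   for large simulation runs where only coefficients and components are
#'   needed).
#' @param st_floor Clipping floor for `1 - G(z)` in the synthetic
#'   transformation.
#' @return A named list of class `plam_control`.
#' @export
plam_control <- function(kernel = "gaussian", grid_min = 0.01, grid_max = 1.5,
                         grid_len = 30, ridge = 1e-8, tol = 0.05,
                         max_iter = 100L, reselect_bandwidths = FALSE,
                         compute_hat = TRUE, st_floor = 1e-10) {
  stopifnot(grid_min > 0, grid_max > grid_min, grid_len >= 1,
            tol > 0, max_iter >= 1)
  structure(list(kernel = kernel, grid_min = grid_min, grid_max = grid_max,
                 grid_len = as.integer(grid_len), ridge = ridge, tol = tol,
                 max_iter = as.integer(max_iter),
                 reselect_bandwidths = isTRUE(reselect_bandwidths),
                 compute_hat = isTRUE(compute_hat), st_floor = st_floor),
            class = "plam_control")
}

# Weighted least-squares coefficients, with a descriptive singularity error.
wls_coef <- function(X, y, w) {
  M <- crossprod(X, w * X)
  tryCatch(solve(M, crossprod(X, w * y)),
           error = function(e) abort("singular parametric design in the coefficient update"))
}

# Solve the additive equation system for smoothers S_1..S_q: the block system
#   f_j + S_j sum_{m != j} f_m = S_j R
# applied to each column of RHS (n x n when building the additive smoother).
# Returns the per-component operator blocks S_j* (list) whose sum S^A maps
# R = Z - X beta to the total additive fit.
additive_operator <- function(Slist) {
  q <- length(Slist)
  n <- nrow(Slist[[1]])
  if (q == 1) return(Slist)
  M <- matrix(0, n * q, n * q)
  RHS <- matrix(0, n * q, n)
  I_n <- diag(n)
  for (j in seq_len(q)) {
    rows <- (j - 1) * n + seq_len(n)
    for (m in seq_len(q)) {
      cols <- (m - 1) * n + seq_len(n)
      M[rows, cols] <- if (m == j) I_n else Slist[[j]]
    }
    RHS[rows, ] <- Slist[[j]]
  }
  Fstack <- tryCatch(solve(M, RHS), error = function(e) {
    abort("additive equation system is singular (concurvity between nonparametric covariates)")
  })
  lapply(seq_len(q), function(j) Fstack[(j - 1) * n + seq_len(n), , drop = FALSE])
}

# Prepare the method-specific working response and weights.
prepare_working <- function(cd, method, k, ref, control) {
  z <- cd_z(cd)
  delta <- cd_delta(cd)
  w <- NULL
  k_used <- NA_integer_
  ref_used <- NA_character_
  if (method == "st") {
    zw <- st_transform(z, delta, floor = control$st_floor)
  } else if (method == "kmw") {
    zw <- z
    ord <- z_order(z, delta)
    w <- numeric(length(z))
    w[ord] <- km_weights(z[ord], delta[ord])
  } else { # knni
    if (is.null(ref)) ref <- select_reference_predictor(cd)
    if (is.null(k)) {
      k <- select_knn_k(cd, ref = ref,
                        control = utils::modifyList(control, list(compute_hat = FALSE)))
    }
    zw <- knn_impute(z, delta, cd[[ref]], k)
    k_used <- as.integer(k)
    ref_used <- ref
  }
  list(z_work = zw, w = w, k = k_used, ref = ref_used)
}

plam_engine <- function(z_work, X, Tm, w, control, bandwidths = NULL) {
  n <- length(z_work)
  q <- ncol(Tm)
  Xd <- cbind(`(Intercept)` = rep(1, n), X)
  ww <- if (is.null(w)) rep(1, n) else w

  searches <- NULL
  if (q > 0 && is.null(bandwidths)) {
    searches <- lapply(seq_len(q), function(j)
      select_bandwidth(Tm[, j], z_work, X = Xd, w = w, control = control))
    bandwidths <- vapply(searches, `[[`, numeric(1), "chosen")
  }
  if (q > 0) {
    Su <- lapply(seq_len(q), function(j)
      llr_smoother(Tm[, j], bandwidths[j], kernel = control$kernel,
                   ridge = control$ridge, obs_weights = w))
    Sc <- lapply(Su, center_smoother)
  } else {
    Su <- Sc <- list()
  }

  f <- matrix(0, n, q)
  beta <- drop(wls_coef(Xd, z_work, ww))
  iter <- 0L
  converged <- (q == 0)
  while (q > 0 && iter < control$max_iter) {
    iter <- iter + 1L
    f_old <- f
    if (control$reselect_bandwidths && iter > 1) {
      for (j in seq_len(q)) {
        r_j <- z_work - drop(Xd %*% beta) - rowSums(f[, -j, drop = FALSE])
        bandwidths[j] <- select_bandwidth(Tm[, j], r_j, X = Xd, w = w,
                                          control = control)$chosen
        Su[[j]] <- llr_smoother(Tm[, j], bandwidths[j], kernel = control$kernel,
                                ridge = control$ridge, obs_weights = w)
        Sc[[j]] <- center_smoother(Su[[j]])
      }
    }
    for (j in seq_len(q)) {
      beta <- drop(wls_coef(Xd, z_work - rowSums(f), ww))
      r_j <- z_work - drop(Xd %*% beta) - rowSums(f[, -j, drop = FALSE])
      f[, j] <- drop(Sc[[j]] %*% r_j)
    }
    change <- mean(abs(f - f_old))
    if (change < control$tol) {
      converged <- TRUE
      break
    }
  }
  if (q > 0 && !converged) {
    warn(paste0("backfitting did not converge in ", control$max_iter, " sweeps"))
  }

  fitted <- drop(Xd %*% beta) + if (q > 0) rowSums(f) else 0
  # final partial residuals and uncentred level offsets, for prediction at
  # new covariate values
  part_resid <- matrix(0, n, q)
  level <- numeric(q)
  for (j in seq_len(q)) {
    part_resid[, j] <- z_work - drop(Xd %*% beta) - rowSums(f[, -j, drop = FALSE])
    level[j] <- mean(drop(Su[[j]] %*% part_resid[, j]))
  }

  hat <- NULL; S_add <- NULL; S_star <- NULL; sigma2 <- NA_real_; df <- NA_real_
  if (control$compute_hat) {
    if (q > 0) {
      S_star <- additive_operator(Sc)
      S_add <- Reduce(`+`, S_star)
    } else {
      S_add <- matrix(0, n, n)
    }
    hat <- hat_matrix(S_add, Xd, w)
    df <- degrees_of_freedom(hat)
    sigma2 <- estimate_variance(z_work, hat)
  }

  list(beta0 = beta[1], beta = beta[-1], beta_full = beta, components = f,
       bandwidths = bandwidths, searches = searches, fitted = fitted,
       residuals = z_work - fitted, iterations = iter, converged = converged,
       smoothers = Sc, smoothers_uncentered = Su, S_star = S_star,
       S_add = S_add, hat = hat, sigma2 = sigma2, df = df,
       part_resid = part_resid, level = level, Xd = Xd, w = w)
}

new_plam <- function(eng, cd, method, prep, control, solver) {
  roles <- cd_roles(cd)
  beta <- eng$beta
  names(beta) <- roles$parametric
  components <- eng$components
  colnames(components) <- roles$nonparametric
  structure(list(
    beta0 = unname(eng$beta0), beta = beta, components = components,
    bandwidths = stats::setNames(eng$bandwidths %||% numeric(0),
                                 roles$nonparametric),
    searches = eng$searches, hat = eng$hat, sigma2 = eng$sigma2, df = eng$df,
    method = method, solver = solver, iterations = eng$iterations,
    converged = eng$converged, fitted = eng$fitted,
    residuals = eng$residuals, z_work = eng$fitted + eng$residuals,
    weights = eng$w, k = prep$k, ref = prep$ref,
    smoothers = eng$smoothers, S_star = eng$S_star, S_add = eng$S_add,
    part_resid = eng$part_resid, level = eng$level,
    data = cd, control = control), class = "plam")
}

#' Fit a partially linear additive model to right-censored data
#'
#' Estimates the model
#' \deqn{E(z \mid x, t) = \beta_0 + x'\beta + \sum_{j=1}^q f_j(t_j)}
#' from right-censored responses by modified backfitting with local linear
#' smoothers. Censoring is handled by one of three working-response
#' solutions: the synthetic data transformation (`"st"`), Kaplan-Meier
#' weighted least squares (`"kmw"`), or k-nearest-neighbour imputation
#' (`"knni"`). Bandwidths are chosen per component by generalized
#' cross-validation on the first sweep and frozen (see [plam_control()]).
#'
#' Each backfitting sweep updates the parametric coefficients by (weighted)
#' least squares on the response with all current additive components
#' removed, then refreshes each component as the centred smooth of its
#' partial residual; iteration stops when the mean absolute change of the
#' component values falls below `tol`. The fixed point coincides with the
#' non-iterative estimator of [plam_noniterative()].
#'
#' @inheritParams censored_data
#' @param method Censorship solution: `"kmw"`, `"st"`, or `"knni"`.
#' @param k Neighbour count for `"knni"`; selected over `2:10` by
#'   [select_knn_k()] when `NULL`.
#' @param ref Reference covariate for `"knni"` distances; defaults to the
#'   parametric column most correlated with the response.
#' @param control A [plam_control()] list.
#' @return An object of class `plam`: a list with elements `beta0`, `beta`
#'   (named coefficients), `components` (`n x q` matrix of mean-zero fitted
#'   component values), `bandwidths`, `hat`, `sigma2`, `df`, `method`,
#'   `iterations`, `converged`, `fitted`, `residuals`, and the data. Use
#'   [tidy()], [glance()], [augment()], [predict.plam()] and [autoplot()].
#' @examples
#' d <- simulate_plam(n = 80, cl = 0.2, seed = 7)
#' fit <- plam(d, parametric = c("x1", "x2"), nonparametric = c("t1", "t2"),
#'             method = "kmw")
#' tidy(fit)
#' @export
plam <- function(data, response = "z", status = "delta",
                 parametric = character(), nonparametric = character(),
                 method = c("kmw", "st", "knni"), k = NULL, ref = NULL,
                 control = plam_control()) {
  method <- match.arg(method)
  cd <- as_censored_data(data, response, status, parametric, nonparametric)
  prep <- prepare_working(cd, method, k, ref, control)
  eng <- plam_engine(prep$z_work, cd_X(cd), cd_T(cd), prep$w, control)
  new_plam(eng, cd, method, prep, control, solver = "backfitting")
}

#' Non-iterative censored PLAM estimator
#'
#' Solves the additive smoothing equation system directly instead of
#' iterating: the per-component operators `S_j*` are obtained by solving the
#' `nq x nq` block system built from the centred smoothers, their sum `S^A`
#' yields `X~ = (I - S^A) X`, `Z~ = (I - S^A) Z`, and the coefficients follow
#' as `(X'W X~)^-1 X'W Z~` (identity weights for the ST and kNNI solutions).
#' Components are recovered as `f_j = S_j* (Z - X beta)` and fitted values as
#' `H^A Z`. Equivalent to the backfitting fixed point; intended as a
#' small-sample reference (the system solve is guarded to `n <= 300`,
#' `q <= 3`).
#'
#' @inheritParams plam
#' @return A `plam` object (with `solver = "noniterative"`).
#' @export
plam_noniterative <- function(data, response = "z", status = "delta",
                              parametric = character(),
                              nonparametric = character(),
                              method = c("kmw", "st", "knni"), k = NULL,
                              ref = NULL, control = plam_control()) {
  method <- match.arg(method)
  cd <- as_censored_data(data, response, status, parametric, nonparametric)
  n <- nrow(cd)
  Tm <- cd_T(cd)
  q <- ncol(Tm)
  if (n > 300 || q > 3) {
    abort("non-iterative solver is guarded to n <= 300 and q <= 3 (the nq x nq system solve); use plam()")
  }
  if (q == 0) abort("non-iterative solver requires at least one nonparametric component")
  prep <- prepare_working(cd, method, k, ref, control)
  z_work <- prep$z_work
  w <- prep$w
  ww <- if (is.null(w)) rep(1, n) else w
  X <- cd_X(cd)
  Xd <- cbind(`(Intercept)` = rep(1, n), X)

  searches <- lapply(seq_len(q), function(j)
    select_bandwidth(Tm[, j], z_work, X = Xd, w = w, control = control))
  bandwidths <- vapply(searches, `[[`, numeric(1), "chosen")
  Su <- lapply(seq_len(q), function(j)
    llr_smoother(Tm[, j], bandwidths[j], kernel = control$kernel,
                 ridge = control$ridge, obs_weights = w))
  Sc <- lapply(Su, center_smoother)

  S_star <- additive_operator(Sc)
  S_add <- Reduce(`+`, S_star)
  Xt <- Xd - S_add %*% Xd
  Zt <- z_work - drop(S_add %*% z_work)
  M <- crossprod(Xd, ww * Xt)
  beta <- tryCatch(drop(solve(M, crossprod(Xd, ww * Zt))), error = function(e) {
    abort("X'W(I - S^A)X is singular; no unique non-iterative solution")
  })
  R <- z_work - drop(Xd %*% beta)
  f <- vapply(S_star, function(Sj) drop(Sj %*% R), numeric(n))
  f <- matrix(f, nrow = n)
  fitted <- drop(Xd %*% beta) + rowSums(f)
  hat <- hat_matrix(S_add, Xd, w)

  part_resid <- matrix(0, n, q)
  level <- numeric(q)
  for (j in seq_len(q)) {
    part_resid[, j] <- R - rowSums(f[, -j, drop = FALSE])
    level[j] <- mean(drop(Su[[j]] %*% part_resid[, j]))
  }

  eng <- list(beta0 = beta[1], beta = beta[-1], beta_full = beta,
              components = f, bandwidths = bandwidths, searches = searches,
              fitted = fitted, residuals = z_work - fitted,
              iterations = NA_integer_, converged = TRUE, smoothers = Sc,
              smoothers_uncentered = Su, S_star = S_star, S_add = S_add,
              hat = hat, df = degrees_of_freedom(hat),
              sigma2 = estimate_variance(z_work, hat),
              part_resid = part_resid, level = level, Xd = Xd, w = w)
  new_plam(eng, cd, method, prep, control, solver = "noniterative")
}

#' @export
print.plam <- function(x, ...) {
  cat(sprintf("<plam> %s solution (%s), n = %d\n",
              toupper(x$method), x$solver, nrow(x$data)))
  cat("  beta0:", format(x$beta0, digits = 4), "\n")
  cat("  beta: ", paste(sprintf("%s = %.4g", names(x$beta), x$beta),
                        collapse = ", "), "\n")
  if (length(x$bandwidths)) {
    cat("  bandwidths:", paste(sprintf("%s: %.4g", names(x$bandwidths),
                                       x$bandwidths), collapse = ", "), "\n")
  }
  if (is.finite(x$sigma2)) {
    cat(sprintf("  sigma^2 = %.4g on %.2f residual df\n", x$sigma2, x$df))
  }
  if (!is.na(x$iterations)) {
    cat(sprintf("  %d backfitting sweep(s), converged: %s\n",
                x$iterations, x$converged))
  }
  invisible(x)
}

#' @describeIn plam Coefficient table: one row per parametric term
#'   (including the intercept) with its estimate.
#' @param x,object A `plam` fit.
#' @param ... Unused.
#' @export
tidy.plam <- function(x, ...) {
  tibble(term = c("(Intercept)", names(x$beta)),
         estimate = c(x$beta0, unname(x$beta)))
}

#' @describeIn plam One-row model summary: method, error variance, residual
#'   degrees of freedom, iterations, convergence flag and bandwidths.
#' @export
glance.plam <- function(x, ...) {
  out <- tibble(method = x$method, solver = x$solver,
                sigma2 = x$sigma2, df = x$df,
                iterations = x$iterations, converged = x$converged)
  bw <- as.list(stats::setNames(x$bandwidths,
                                paste0("h_", names(x$bandwidths))))
  dplyr::bind_cols(out, tibble::as_tibble(bw))
}

#' @describeIn plam Original data plus `.fitted`, `.resid` (on the working
#'   response scale) and one `.f_<name>` column per nonparametric component.
#' @export
augment.plam <- function(x, ...) {
  out <- as_tibble(x$data)
  out$.fitted <- x$fitted
  out$.resid <- x$residuals
  comp <- x$components
  for (j in seq_len(ncol(comp))) {
    out[[paste0(".f_", colnames(comp)[j])]] <- comp[, j]
  }
  out
}

#' Predict from a censored PLAM fit
#'
#' Without `newdata`, returns the in-sample fitted values `H^A z`. With
#' `newdata`, evaluates the linear predictor at the new parametric covariates
#' and each component at the new nonparametric covariates by constructing a
#' fresh local linear weight row (at the stored bandwidth) over the training
#' points, minus the component's training-sample level so components stay
#' mean-zero. Values outside the observed covariate ranges trigger an
#' extrapolation warning.
#'
#' @param object A `plam` fit.
#' @param newdata Optional data frame with the model's covariate columns.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.plam <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  roles <- cd_roles(object$data)
  p <- roles$parametric
  qn <- roles$nonparametric
  miss <- setdiff(c(p, qn), names(newdata))
  if (length(miss)) abort(paste0("newdata lacks column(s): ",
                                 paste(miss, collapse = ", ")))
  out <- rep(object$beta0, nrow(newdata))
  if (length(p)) {
    out <- out + drop(as.matrix(newdata[p]) %*% object$beta)
  }
  K <- kernel_fun(object$control$kernel)
  for (j in seq_along(qn)) {
    t_train <- object$data[[qn[j]]]
    t_new <- newdata[[qn[j]]]
    if (any(t_new < min(t_train) | t_new > max(t_train))) {
      warn(paste0("extrapolating `", qn[j], "` beyond the observed range"))
    }
    h <- object$bandwidths[j]
    r_j <- object$part_resid[, j]
    ow <- if (is.null(object$weights)) rep(1, length(t_train)) else object$weights
    fj_new <- vapply(t_new, function(m) {
      k <- ow * K((t_train - m) / h) / h
      s0 <- sum(k); s1 <- sum(k * (t_train - m)); s2 <- sum(k * (t_train - m)^2)
      det <- s0 * s2 - s1^2
      if (det <= 0) det <- det + object$control$ridge
      sum(k * (s2 - (t_train - m) * s1) / det * r_j)
    }, numeric(1))
    out <- out + fj_new - object$level[j]
  }
  out
}

#' @export
fitted.plam <- function(object, ...) object$fitted

#' @export
residuals.plam <- function(object, ...) object$residuals

#' @export
coef.plam <- function(object, ...) c(`(Intercept)` = object$beta0, object$beta)
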