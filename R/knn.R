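#' Choose the reference predictor for kNN imputation
#'
#' The kNN imputation of censored responses measures distance on a single
#' parametric covariate strongly associated with the response. This returns
#' the parametric column with the largest absolute Pearson correlation with
#' the response, computed over uncensored rows only (censored `z` understate
#' the lifetime and would distort the correlation). Zero-variance columns are
#' skipped; if every column is degenerate an error is raised.
#'
#' @inheritParams censored_data
#' @return The name of the selected column.
#' @export
select_reference_predictor <- function(data, response = "z", status = "delta",
                                       parametric = character(),
                                       nonparametric = character()) {
  cd <- as_censored_data(data, response, status, parametric, nonparametric)
  pn <- cd_roles(cd)$parametric
  if (!length(pn)) abort("at least one parametric covariate is required")
  z <- cd_z(cd)
  delta <- cd_delta(cd)
  unc <- delta == 1
  X <- cd_X(cd)[unc, , drop = FALSE]
  zu <- z[unc]
  cors <- vapply(seq_along(pn), function(j) {
    xj <- X[, j]
    if (stats::sd(xj) == 0 || stats::sd(zu) == 0) return(NA_real_)
    abs(cor(xj, zu))
  }, numeric(1))
  if (all(is.na(cors))) abort("all parametric covariates have zero variance over uncensored rows")
  pn[which.max(cors)]
}

#' Impute censored responses by k nearest uncensored neighbours
#'
#' For each censored observation, the Euclidean distance on the reference
#' covariate to every other row is computed, rows are sorted by ascending
#' distance (ties kept in row order), and the censored response is replaced
#' by the mean of the first `k` uncensored responses. Uncensored rows pass
#' through unchanged.
#'
#' @inheritParams km_curve
#' @param x_ref Numeric reference covariate (see
#'   [select_reference_predictor()]).
#' @param k Neighbour count, between 2 and the number of uncensored rows.
#' @return Numeric vector: `z` with censored entries imputed.
#' @examples
#' knn_impute(z = c(3, 4, 0.5, 8, 9), delta = c(1, 1, 0, 1, 1),
#'            x_ref = c(0, 1, 2, 10, 11), k = 2)
#' @export
knn_impute <- function(z, delta, x_ref, k) {
  stopifnot(length(z) == length(delta), length(x_ref) == length(z),
            all(delta %in% c(0, 1)))
  k <- as.integer(k)
  n_unc <- sum(delta == 1)
  if (k < 2) abort("`k` must be at least 2")
  if (k > n_unc) {
    abort(paste0("fewer than k = ", k, " uncensored rows (", n_unc, ") available"))
  }
  out <- z
  for (i in which(delta == 0)) {
    d <- abs(x_ref - x_ref[i])
    ord <- order(d)                      # stable: distance ties keep row order
    neigh <- ord[delta[ord] == 1][seq_len(k)]
    out[i] <- mean(z[neigh])
  }
  out
}

#' Select the kNN neighbour count by in-sample residual MSE
#'
#' Runs the full censored PLAM fit (kNN imputation followed by backfitting)
#' for each candidate `k` and returns the one minimising the in-sample mean
#' squared residual of the fit against the imputed response. Ties go to the
#' smallest `k`. The true response is unobservable for censored rows, so an
#' in-sample criterion on the working response is used.
#'
#' @inheritParams censored_data
#' @param k_range Integer candidates, default `2:10`, intersected with the
#'   feasible range (at most the number of uncensored rows).
#' @param ref Reference covariate column; defaults to
#'   [select_reference_predictor()].
#' @param control A [plam_control()] list for the inner fits.
#' @return The selected integer `k`.
#' @export
select_knn_k <- function(data, response = "z", status = "delta",
                         parametric = character(), nonparametric = character(),
                         k_range = 2:10, ref = NULL,
                         control = plam_control()) {
  cd <- as_censored_data(data, response, status, parametric, nonparametric)
  n_unc <- sum(cd_delta(cd) == 1)
  ks <- sort(unique(as.integer(k_range)))
  ks <- ks[ks >= 2 & ks <= n_unc]
  if (!length(ks)) abort("no feasible k in `k_range`")
  if (length(ks) == 1) return(ks)
  if (is.null(ref)) ref <- select_reference_predictor(cd)
  mse <- vapply(ks, function(k) {
    fit <- plam(cd, method = "knni", k = k, ref = ref, control = control)
    mean(fit$residuals^2)
  }, numeric(1))
  ks[which.min(mse)]   # which.min returns the first (smallest k) on ties
}
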