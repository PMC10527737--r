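#' Product-limit (Kaplan-Meier) estimate of the censoring or lifetime
#' distribution
#'
#' Computes the Kaplan-Meier step-function estimate of either the censoring
#' distribution `G` (jumps at censored observations) or the lifetime
#' distribution `F` (jumps at uncensored observations) from right-censored
#' pairs `(z, delta)`. The returned survival values are
#' \deqn{1 - \hat G(u) = \prod_{i:\, z_{(i)} \le u,\ \delta_{(i)} = 0}
#'   \frac{n-i}{n-i+1},}
#' evaluated right-continuously, with the product over uncensored order
#' statistics instead when `kind = "lifetime"`. Ties between censored and
#' uncensored observations at equal `z` are broken with the uncensored
#' observation first (standard product-limit convention).
#'
#' @param z Numeric vector of observed responses `min(y, c)`.
#' @param delta 0/1 censoring indicator (1 = event observed).
#' @param kind `"censoring"` to estimate `G` (the default, as used by the
#'   synthetic data transformation) or `"lifetime"` to estimate `F`.
#'
#' @return A `km_curve` tibble with columns `time` (ascending jump locations)
#'   and `surv` (the survival value from that time onward); attributes `kind`
#'   and `n`. The curve equals 1 before the first jump. A `degenerate`
#'   attribute flags curves that reach 0.
#' @seealso [st_transform()], [km_weights()], [km_survival()]
#' @examples
#' km_curve(c(1, 2, 3), c(1, 0, 1))
#' @export
km_curve <- function(z, delta, kind = c("censoring", "lifetime")) {
  kind <- match.arg(kind)
  stopifnot(length(z) == length(delta), all(delta %in% c(0, 1)))
  n <- length(z)
  ord <- z_order(z, delta)
  zs <- z[ord]
  ds <- delta[ord]
  jump <- if (kind == "censoring") ds == 0 else ds == 1
  i <- seq_len(n)
  factor <- ifelse(jump, (n - i) / (n - i + 1), 1)
  s <- cumprod(factor)
  times <- zs[jump]
  surv <- s[jump]
  # collapse tied jump times to the final (smallest) survival value
  if (length(times) > 1) {
    keep <- !duplicated(times, fromLast = TRUE)
    times <- times[keep]
    surv <- surv[keep]
  }
  out <- tibble(time = times, surv = surv)
  structure(out,
            class = c("km_curve", class(out)),
            kind = kind, n = n,
            degenerate = length(surv) > 0 && min(surv) <= 0)
}

#' Evaluate a product-limit curve
#'
#' Right-continuous evaluation of a [km_curve()] step function: the survival
#' value at `u` includes the jump at `u` itself.
#'
#' @param curve A `km_curve`.
#' @param u Numeric vector of evaluation points.
#' @return Numeric vector of survival values (`1 - G(u)` or `1 - F(u)`).
#' @export
km_survival <- function(curve, u) {
  stopifnot(inherits(curve, "km_curve"))
  if (nrow(curve) == 0) return(rep(1, length(u)))
  idx <- findInterval(u, curve$time)
  c(1, curve$surv)[idx + 1]
}

#' Synthetic data transformation for right-censored responses
#'
#' Rescales the observed responses by the inverse probability of not being
#' censored, producing the synthetic response
#' \deqn{z_i^G = \frac{\delta_i z_i}{1 - \hat G(z_i)},}
#' which has the same conditional mean as the uncensored lifetime and can be
#' fed to ordinary least-squares machinery. Censored points map exactly to 0;
#' with no censoring the transformation is the identity.
#'
#' @inheritParams km_curve
#' @param curve Optional precomputed censoring [km_curve()]; estimated from
#'   `(z, delta)` when omitted.
#' @param floor Positive lower bound applied to `1 - G(z_i)` before division
#'   (guards a censored tie at the sample maximum); values clipped trigger a
#'   warning. An uncensored point at which `1 - G` is exactly 0 is an error.
#' @return Numeric vector of synthetic responses, same length as `z`.
#' @examples
#' st_transform(c(1, 2, 3), c(1, 0, 1))  # c(1, 0, 6)
#' @export
st_transform <- function(z, delta, curve = NULL, floor = 1e-10) {
  stopifnot(length(z) == length(delta), all(delta %in% c(0, 1)))
  if (is.null(curve)) curve <- km_curve(z, delta, kind = "censoring")
  if (!identical(attr(curve, "kind"), "censoring")) {
    abort("`curve` must estimate the censoring distribution (kind = \"censoring\")")
  }
  denom <- km_survival(curve, z)
  unc <- delta == 1
  if (any(unc & denom == 0)) {
    bad <- which(unc & denom == 0)
    abort(paste0("1 - G(z) is exactly 0 at uncensored observation(s) ",
                 paste(bad, collapse = ", "),
                 "; tail observation unusable for the synthetic transformation"))
  }
  if (any(unc & denom < floor)) {
    warn("1 - G(z) below floor at some uncensored points; clipping")
    denom <- pmax(denom, floor)
  }
  out <- numeric(length(z))
  out[unc] <- z[unc] / denom[unc]
  out
}

#' Kaplan-Meier weights for weighted least squares
#'
#' Computes the jumps of the product-limit estimate of the lifetime
#' distribution,
#' \deqn{w_i = \frac{\delta_i}{n-i+1} \prod_{r=1}^{i-1}
#'   \left(\frac{n-r}{n-r+1}\right)^{\delta_r},}
#' used as observation weights in censored weighted least squares. The input
#' must already be sorted ascending in `z` (uncensored first at ties): the
#' formula is order-dependent and an unsorted input is an error. Censored
#' observations receive weight 0; the weights sum to 1 exactly when the
#' largest observation is uncensored and never exceed 1. With no censoring
#' every weight equals `1/n`.
#'
#' @inheritParams km_curve
#' @return Numeric weight vector aligned to the (sorted) rows.
#' @examples
#' km_weights(c(1, 2, 3), c(1, 0, 1))  # c(1/3, 0, 2/3)
#' @export
km_weights <- function(z, delta) {
  stopifnot(length(z) == length(delta), all(delta %in% c(0, 1)))
  n <- length(z)
  if (!identical(z_order(z, delta), seq_len(n))) {
    abort("`z` must be sorted ascending (uncensored first at tied values); the Kaplan-Meier weight formula is order-dependent")
  }
  r <- seq_len(n)
  cp <- cumprod(((n - r) / (n - r + 1))^delta)
  lag_cp <- c(1, cp[-n])
  delta / (n - r + 1) * lag_cp
}

#' Apply a censorship adjustment to a dataset
#'
#' Data-frame front end to the three censorship solutions. Adds to `data` the
#' column the chosen method feeds into the least-squares fit: `z_st`
#' (synthetic response, [st_transform()]), `w_kmw` (Kaplan-Meier weight in the
#' original row order, [km_weights()]), or `z_knn` (k-nearest-neighbour
#' imputed response, [knn_impute()]).
#'
#' @inheritParams censored_data
#' @param method One of `"st"`, `"kmw"`, `"knni"`.
#' @param k Neighbour count for `"knni"`; when `NULL` it is selected over
#'   `2:10` by [select_knn_k()] (which requires model roles to be declared).
#' @param ref Reference covariate column for `"knni"`; defaults to the
#'   parametric column most correlated with the response over uncensored rows.
#' @return `data` as a tibble with the added adjustment column.
#' @export
censor_adjust <- function(data, method = c("st", "kmw", "knni"),
                          response = "z", status = "delta",
                          parametric = character(), nonparametric = character(),
                          k = NULL, ref = NULL) {
  method <- match.arg(method)
  cd <- as_censored_data(data, response, status, parametric, nonparametric)
  z <- cd_z(cd)
  delta <- cd_delta(cd)
  out <- as_tibble(data)
  if (method == "st") {
    out$z_st <- st_transform(z, delta)
  } else if (method == "kmw") {
    ord <- z_order(z, delta)
    w <- numeric(length(z))
    w[ord] <- km_weights(z[ord], delta[ord])
    out$w_kmw <- w
  } else {
    if (is.null(ref)) {
      ref <- select_reference_predictor(cd)
    }
    if (is.null(k)) {
      k <- select_knn_k(cd, ref = ref)
    }
    out$z_knn <- knn_impute(z, delta, data[[ref]], k)
  }
  out
}
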