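#' Assemble and validate a right-censored modelling dataset
#'
#' Bundles a response observed under right censoring, `z = min(y, c)`, its
#' censoring indicator (`1` = event observed, `0` = censored), parametric
#' covariates entering the model linearly, and nonparametric covariates each
#' modelled by a smooth function. All downstream fitting functions accept the
#' object returned here (or build it internally from the same arguments).
#'
#' @param data A data frame with one row per subject.
#' @param response Name of the response column (`z`, the possibly censored,
#'   possibly log-scale lifetime). Default `"z"`.
#' @param status Name of the 0/1 censoring-indicator column (1 = uncensored).
#'   Default `"delta"`.
#' @param parametric Character vector of parametric covariate column names.
#' @param nonparametric Character vector of nonparametric covariate column
#'   names.
#'
#' @return A `censored_data` object: a tibble restricted to the declared
#'   columns, with role metadata in attributes (`response`, `status`,
#'   `parametric`, `nonparametric`) and a `sorted_by_z` flag.
#' @examples
#' d <- tibble::tibble(z = c(2, 1, 3), delta = c(1, 0, 1),
#'                     x1 = rnorm(3), t1 = c(.1, .5, .9))
#' censored_data(d, parametric = "x1", nonparametric = "t1")
#' @export
censored_data <- function(data, response = "z", status = "delta",
                          parametric = character(), nonparametric = character()) {
  stopifnot(is.data.frame(data))
  cols <- c(response, status, parametric, nonparametric)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort(paste0("column(s) not found in `data`: ",
                 paste(missing_cols, collapse = ", ")))
  }
  roles <- list(response = response, status = status,
                parametric = parametric, nonparametric = nonparametric)
  if (anyDuplicated(cols)) {
    abort("response, status, parametric and nonparametric columns must be disjoint")
  }
  out <- as_tibble(data[cols])
  for (nm in cols) {
    if (!is.numeric(out[[nm]])) {
      abort(paste0("column `", nm, "` must be numeric"))
    }
  }
  if (anyNA(out)) {
    bad <- which(!complete.cases(out))
    abort(paste0("missing values in row(s): ", paste(bad, collapse = ", ")))
  }
  delta <- out[[status]]
  if (!all(delta %in% c(0, 1))) {
    bad <- which(!delta %in% c(0, 1))
    abort(paste0("`", status, "` must be 0/1; offending row(s): ",
                 paste(bad, collapse = ", ")))
  }
  if (nrow(out) < 3) abort("need at least 3 observations")
  if (!any(delta == 1)) abort("all observations are censored; no events to fit")
  z <- out[[response]]
  structure(out,
            class = c("censored_data", class(out)),
            roles = roles,
            sorted_by_z = !is.unsorted(z))
}

#' @export
print.censored_data <- function(x, ...) {
  roles <- attr(x, "roles")
  delta <- x[[roles$status]]
  cat(sprintf("<censored_data> n = %d, censored = %d (%.1f%%)\n",
              nrow(x), sum(delta == 0), 100 * mean(delta == 0)))
  cat(sprintf("  response: %s  status: %s\n", roles$response, roles$status))
  cat(sprintf("  parametric: %s\n", paste(roles$parametric, collapse = ", ")))
  cat(sprintf("  nonparametric: %s\n", paste(roles$nonparametric, collapse = ", ")))
  NextMethod()
}

cd_roles <- function(data) attr(data, "roles")

cd_z <- function(data) data[[cd_roles(data)$response]]
cd_delta <- function(data) data[[cd_roles(data)$status]]
cd_X <- function(data) {
  p <- cd_roles(data)$parametric
  if (!length(p)) return(matrix(numeric(), nrow(data), 0))
  as.matrix(data[p])
}
cd_T <- function(data) {
  q <- cd_roles(data)$nonparametric
  if (!length(q)) return(matrix(numeric(), nrow(data), 0))
  as.matrix(data[q])
}

# Coerce loose arguments to censored_data if needed.
as_censored_data <- function(data, response, status, parametric, nonparametric) {
  if (inherits(data, "censored_data")) return(data)
  censored_data(data, response, status, parametric, nonparametric)
}

# Order rows ascending in z; ties broken so that uncensored (delta = 1)
# observations precede censored ones at equal z (product-limit convention).
# Returns the permutation.
z_order <- function(z, delta) order(z, -delta)
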