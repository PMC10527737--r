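#' Read a right-censored dataset from delimited text
#'
#' Reads a CSV with named columns, validates it, and returns a
#' [censored_data()] object. The status column must be strictly 0/1 and all
#' declared columns numeric; offending rows are named in the error. Rows
#' containing missing values are dropped with a warning listing their row
#' numbers.
#'
#' @param path Path to a CSV file with a header row.
#' @inheritParams censored_data
#' @return A `censored_data` object.
#' @export
read_censored_csv <- function(path, response = "z", status = "delta",
                              parametric = NULL, nonparametric = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(parametric)) {
    parametric <- grep("^x[0-9]*$", names(df), value = TRUE)
  }
  if (is.null(nonparametric)) {
    nonparametric <- grep("^t[0-9]*$", names(df), value = TRUE)
  }
  cols <- c(response, status, parametric, nonparametric)
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    abort(paste0("column(s) not found in ", path, ": ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (nm in cols) {
    if (!is.numeric(df[[nm]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[nm]]))) & !is.na(df[[nm]]))
      abort(paste0("non-numeric values in column `", nm, "`",
                   if (length(bad)) paste0(" at row(s) ",
                                           paste(utils::head(bad, 5), collapse = ", "))))
    }
  }
  incomplete <- !complete.cases(df[cols])
  if (any(incomplete)) {
    warn(paste0("dropping row(s) with missing values: ",
                paste(which(incomplete), collapse = ", ")))
    df <- df[!incomplete, , drop = FALSE]
  }
  censored_data(df, response = response, status = status,
                parametric = parametric, nonparametric = nonparametric)
}

#' Write a fitted censored PLAM to CSV
#'
#' Serialises a [plam()] fit as a long-format CSV with columns
#' `section, name, row, value`: section `coef` holds the intercept and
#' parametric coefficients (`row` empty), section `component` the per-row
#' fitted component values (one `name` per nonparametric covariate), section
#' `fitted` the per-row fitted values, and section `diagnostic` the scalars
#' (`sigma2`, `df`, `iterations`, `converged`, one `h_<name>` bandwidth per
#' component, and `k` for the kNNI solution). [read_plam_csv()] parses the
#' file back.
#'
#' @param fit A `plam` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_plam_csv <- function(fit, path) {
  stopifnot(inherits(fit, "plam"))
  coef_tbl <- tibble(section = "coef",
                     name = c("(Intercept)", names(fit$beta)),
                     row = NA_integer_,
                     value = c(fit$beta0, unname(fit$beta)))
  comp <- fit$components
  comp_tbl <- NULL
  if (ncol(comp) > 0) {
    comp_tbl <- dplyr::bind_rows(lapply(colnames(comp), function(nm) {
      tibble(section = "component", name = nm, row = seq_len(nrow(comp)),
             value = comp[, nm])
    }))
  }
  fit_tbl <- tibble(section = "fitted", name = "fitted",
                    row = seq_along(fit$fitted), value = fit$fitted)
  diag_vals <- c(sigma2 = fit$sigma2, df = fit$df,
                 iterations = as.numeric(fit$iterations),
                 converged = as.numeric(fit$converged),
                 stats::setNames(unname(fit$bandwidths),
                                 paste0("h_", names(fit$bandwidths))))
  if (!is.na(fit$k)) diag_vals <- c(diag_vals, k = as.numeric(fit$k))
  diag_tbl <- tibble(section = "diagnostic", name = names(diag_vals),
                     row = NA_integer_, value = unname(diag_vals))
  out <- dplyr::bind_rows(coef_tbl, comp_tbl, fit_tbl, diag_tbl)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plam_csv
#' @return For `read_plam_csv`: a list with `beta0`, `beta` (named vector),
#'   `components` (matrix), `fitted`, and `diagnostics` (named vector).
#' @export
read_plam_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("section", "name", "row", "value") %in% names(df)))
  coefs <- df[df$section == "coef", ]
  comps <- df[df$section == "component", ]
  comp_mat <- NULL
  if (nrow(comps)) {
    nms <- unique(comps$name)
    comp_mat <- vapply(nms, function(nm) {
      sub <- comps[comps$name == nm, ]
      sub$value[order(sub$row)]
    }, numeric(sum(comps$name == comps$name[1])))
  }
  diagn <- df[df$section == "diagnostic", ]
  fitted <- df[df$section == "fitted", ]
  list(beta0 = coefs$value[coefs$name == "(Intercept)"],
       beta = stats::setNames(coefs$value[coefs$name != "(Intercept)"],
                              coefs$name[coefs$name != "(Intercept)"]),
       components = comp_mat,
       fitted = fitted$value[order(fitted$row)],
       diagnostics = stats::setNames(diagn$value, diagn$name))
}
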