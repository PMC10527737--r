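#' Plot a product-limit curve
#'
#' Step plot of the Kaplan-Meier estimate stored in a [km_curve()].
#'
#' @param object A `km_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.km_curve <- function(object, ...) {
  kind <- attr(object, "kind")
  df <- dplyr::bind_rows(
    tibble(time = min(object$time) - 0.05 * diff(range(object$time, 0)),
           surv = 1),
    as_tibble(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time",
                  y = if (kind == "censoring") "1 - G(u)" else "1 - F(u)",
                  title = paste("Product-limit estimate:", kind,
                                "distribution")) +
    ggplot2::theme_minimal()
}

#' Plot the fitted nonparametric components
#'
#' One facet per nonparametric covariate: the fitted component curve over
#' the observed covariate values, with the component's partial residuals as
#' points.
#'
#' @param object A `plam` fit.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.plam <- function(object, ...) {
  roles <- cd_roles(object$data)
  qn <- roles$nonparametric
  parts <- dplyr::bind_rows(lapply(seq_along(qn), function(j) {
    tibble(component = qn[j], t = object$data[[qn[j]]],
           f_hat = object$components[, j],
           partial = object$part_resid[, j] -
             mean(object$part_resid[, j]))
  }))
  ggplot2::ggplot(parts, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$partial),
                        alpha = 0.35, size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$f_hat), colour = "#2c7fb8",
                       linewidth = 0.9) +
    ggplot2::facet_wrap(~component, scales = "free") +
    ggplot2::labs(x = "covariate", y = "component",
                  title = paste0("Fitted additive components (",
                                 toupper(object$method), " solution)")) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.plam
#' @param fit A `plam` fit.
#' @export
plot_components <- function(fit, ...) autoplot.plam(fit, ...)

#' Plot Monte-Carlo scenario metrics
#'
#' Dot plot of the aggregated metrics of a [run_scenario()] result, one
#' facet per metric, methods on the x axis.
#'
#' @param object A `plam_scenario`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.plam_scenario <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$value)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(
      x = "censorship solution", y = "value",
      title = sprintf("Scenario metrics (n = %d, CL = %g%%, %d reps)",
                      object$config$n, 100 * object$config$cl,
                      object$config$reps)) +
    ggplot2::theme_minimal()
}

#' Plot a GCV bandwidth search
#'
#' @param object A `bandwidth_search` from [select_bandwidth()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bandwidth_search <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df[is.finite(df$gcv), ],
                  ggplot2::aes(x = .data$h, y = .data$gcv)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = df[df$chosen, ], colour = "#d95f02", size = 2) +
    ggplot2::labs(x = "bandwidth h", y = "GCV score",
                  title = "GCV bandwidth search") +
    ggplot2::theme_minimal()
}
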