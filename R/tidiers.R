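#' Tidy a penalized B-spline fit
#'
#' @param x A `penalized_fit`.
#' @param ... Unused.
#' @return A tibble with one row per basis coefficient.
#' @method tidy penalized_fit
#' @export
tidy.penalized_fit <- function(x, ...) {
  tibble::tibble(term = paste0("b", seq_along(x$coefficients)),
                 estimate = x$coefficients)
}

#' One-row summary of a penalized B-spline fit
#'
#' @param x A `penalized_fit`.
#' @param ... Unused.
#' @return A one-row tibble: basis size, penalty, effective degrees of
#'   freedom, GCV index, residual sum of squares, sample size.
#' @method glance penalized_fit
#' @export
glance.penalized_fit <- function(x, ...) {
  tibble::tibble(n_basis = x$basis$n_basis, order = x$basis$order,
                 lambda = x$lambda, dof = x$dof, gcv = x$gcv,
                 sse = x$sse, n = x$n)
}

#' Tidy an AR error model
#'
#' @param x An `ar_model`.
#' @param ... Unused.
#' @return A tibble with one row per AR coefficient (empty for order 0).
#' @method tidy ar_model
#' @export
tidy.ar_model <- function(x, ...) {
  tibble::tibble(term = if (x$order) paste0("beta", seq_len(x$order))
                 else character(0),
                 estimate = x$beta)
}

#' One-row summary of an AR error model
#'
#' @param x An `ar_model`.
#' @param ... Unused.
#' @return A one-row tibble: order, innovation variance, BIC, stationarity.
#' @method glance ar_model
#' @export
glance.ar_model <- function(x, ...) {
  tibble::tibble(order = x$order, innovation_var = x$innovation_var,
                 bic = x$bic, stationary = x$stationary)
}

#' One-row summary of a smoothed EDA profile
#'
#' @param x An `eda_smooth`.
#' @param ... Unused.
#' @return A one-row tibble describing the fit: method, grid size and the
#'   method's tuning parameters (penalty/dof/GCV for the spline smoother;
#'   bandwidths, degree and AR order for local polynomial regression).
#' @method glance eda_smooth
#' @export
glance.eda_smooth <- function(x, ...) {
  m <- meta_of(x)
  base <- tibble::tibble(method = m$method, n_grid = nrow(x),
                         t_min = x$t[1], t_max = x$t[nrow(x)])
  if (identical(m$method, "fda")) {
    dplyr::bind_cols(base, tibble::tibble(
      n_basis = m$fit$basis$n_basis, lambda = m$lambda,
      dof = m$dof, gcv = m$gcv))
  } else {
    dplyr::bind_cols(base, tibble::tibble(
      degree = m$degree, h_initial = m$h_initial %||% m$h,
      h_final = m$h_final %||% m$h,
      ar_order = if (!is.null(m$ar)) m$ar$order else NA_integer_))
  }
}

#' @export
print.eda_pipeline_result <- function(x, ...) {
  cat(sprintf("<eda_pipeline_result: %d feature row(s), %d failure(s)>\n",
              nrow(x$features), nrow(x$failures)))
  print(x$features, ...)
  invisible(x)
}

#' @export
print.fir_filter <- function(x, ...) {
  cat(sprintf("<fir_filter: %d taps, cutoff %g Hz at %g Hz sampling>\n",
              x$n_taps, x$cutoff, x$sample_rate))
  invisible(x)
}

#' @export
print.ar_model <- function(x, ...) {
  cat(sprintf("<ar_model: order %d, innovation sd %.4g%s>\n", x$order,
              sqrt(x$innovation_var),
              if (!x$stationary) ", NON-STATIONARY" else ""))
  if (x$order) cat("  beta:", signif(x$beta, 4), "\n")
  invisible(x)
}

#' @export
print.penalized_fit <- function(x, ...) {
  cat(sprintf(
    "<penalized_fit: %d basis fns (order %d), lambda %.3g, dof %.2f, GCV %.4g>\n",
    x$basis$n_basis, x$basis$order, x$lambda, x$dof, x$gcv))
  invisible(x)
}
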