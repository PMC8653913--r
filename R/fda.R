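#' Equally spaced B-spline knots over a time span
#'
#' Places `n_interior` interior knots at equal spacing strictly inside
#' `[t0, t1]`, with boundary knots at the endpoints repeated to the spline
#' order.  The resulting basis has `n_interior + order` functions.
#'
#' @param span Numeric length-2 vector `c(t0, t1)` in seconds.
#' @param n_interior Number of interior knots (>= 1).
#' @param order Spline polynomial order `m` (default 4, i.e. cubic).
#' @return A `bspline_basis`: list with `order`, `interior`, `boundary`,
#'   `knots` (the full knot vector with boundary multiplicity `order`) and
#'   `n_basis`.
#' @export
#' @examples
#' b <- make_equispaced_knots(c(0, 300), n_interior = 9)
#' b$n_basis      # 13
#' b$interior     # 30, 60, ..., 270
make_equispaced_knots <- function(span, n_interior, order = 4L) {
  stopifnot(length(span) == 2L, is_number(order), order >= 2)
  t0 <- span[1]; t1 <- span[2]
  if (!(t1 > t0)) {
    stop_edapeaks("span must have t1 > t0", "edapeaks_parameter_error")
  }
  if (!is_number(n_interior) || n_interior < 1) {
    stop_edapeaks("n_interior must be >= 1 (pure polynomial not supported)",
                  "edapeaks_parameter_error")
  }
  n_interior <- as.integer(n_interior)
  interior <- t0 + (t1 - t0) * seq_len(n_interior) / (n_interior + 1L)
  structure(list(
    order = as.integer(order),
    interior = interior,
    boundary = c(t0, t1),
    knots = c(rep(t0, order), interior, rep(t1, order)),
    n_basis = n_interior + as.integer(order)),
    class = "bspline_basis")
}

# curvature penalty matrix: integral of B_i''(t) B_j''(t) dt over the span.
# B'' is piecewise polynomial of degree order-3, so Gauss-Legendre with
# order-2 nodes per inter-breakpoint interval is exact.
penalty_matrix <- function(basis) {
  brk <- unique(c(basis$boundary[1], basis$interior, basis$boundary[2]))
  ng <- max(2L, basis$order - 2L)
  gl <- gauss_legendre(ng)
  K <- matrix(0, basis$n_basis, basis$n_basis)
  for (i in seq_len(length(brk) - 1L)) {
    a <- brk[i]; b <- brk[i + 1L]
    xg <- (b - a) / 2 * gl$nodes + (a + b) / 2
    wg <- (b - a) / 2 * gl$weights
    B2 <- splines::splineDesign(basis$knots, xg, ord = basis$order,
                                derivs = rep(2L, length(xg)))
    K <- K + crossprod(B2, B2 * wg)
  }
  (K + t(K)) / 2
}

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenvalue
# method (exact for polynomials of degree 2n - 1)
gauss_legendre <- function(n) {
  if (n == 1L) return(list(nodes = 0, weights = 2))
  k <- seq_len(n - 1L)
  beta <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1L)] <- beta
  J[cbind(k + 1L, k)] <- beta
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx], weights = 2 * e$vectors[1, idx]^2)
}

#' Fit a roughness-penalized B-spline to a normalized EDA profile
#'
#' Minimizes the penalized sum of squares
#' \deqn{\sum_i (y_i - f(t_i))^2 + \lambda \int f''(t)^2 \, dt}
#' over splines in the given basis.  The generalized cross-validation index
#' `GCV = n * SSE / (n - dof)^2` with `dof` the trace of the smoother map is
#' returned for tuning-parameter selection.
#'
#' @param profile An `eda_profile` (columns `elapsed`, `value`), or any
#'   tibble with those columns.
#' @param basis A `bspline_basis` from [make_equispaced_knots()].
#' @param lambda Roughness penalty weight, >= 0.
#' @return A `penalized_fit` object (see [tidy.penalized_fit()],
#'   [glance.penalized_fit()]).
#' @export
fit_penalized_spline <- function(profile, basis, lambda) {
  stopifnot(inherits(basis, "bspline_basis"), is_number(lambda), lambda >= 0)
  x <- profile$elapsed
  y <- profile$value
  n <- length(x)
  if (length(unique(x)) < basis$n_basis) {
    stop_edapeaks(sprintf(
      "need at least n_basis = %d distinct time points (have %d)",
      basis$n_basis, length(unique(x))), "edapeaks_parameter_error")
  }
  brk <- c(basis$boundary[1], basis$interior, basis$boundary[2])
  counts <- tabulate(findInterval(x, brk, rightmost.closed = TRUE),
                     nbins = length(brk) - 1L)
  if (lambda == 0 && any(counts == 0L)) {
    j <- which(counts == 0L)[1]
    stop_edapeaks(sprintf(
      "no data in knot span [%g, %g]; design is rank deficient",
      brk[j], brk[j + 1L]), "edapeaks_rank_deficient")
  }
  B <- splines::splineDesign(basis$knots, x, ord = basis$order)
  K <- penalty_matrix(basis)
  BtB <- crossprod(B)
  # normalize the curvature penalty to the design scale so lambda is
  # dimensionless: the same grid of lambda values then behaves comparably
  # across time spans and sampling rates
  pen_scale <- sum(diag(BtB)) / max(sum(diag(K)), .Machine$double.eps)
  M <- BtB + lambda * pen_scale * K
  cf <- tryCatch(solve(M, crossprod(B, y)),
                 error = function(e) stop_edapeaks(
                   paste0("penalized normal equations are singular: ",
                          conditionMessage(e)), "edapeaks_rank_deficient"))
  fitted <- drop(B %*% cf)
  res <- y - fitted
  sse <- sum(res^2)
  dof <- sum(diag(solve(M, BtB)))
  gcv <- if (n - dof > 1e-8) n * sse / (n - dof)^2 else Inf
  structure(list(
    basis = basis, coefficients = drop(cf), lambda = lambda,
    gcv = gcv, dof = dof, sse = sse, n = n,
    x = x, y = y, fitted = fitted, residuals = res),
    class = "penalized_fit")
}

#' Select the roughness penalty by generalized cross-validation
#'
#' Fits the profile at every value of a log-spaced lambda grid and returns
#' the fit minimizing the GCV index; the whole GCV profile is kept in
#' `$gcv_profile`.
#'
#' @inheritParams fit_penalized_spline
#' @param lambda_grid Positive penalty values; at least 5, spanning at least
#'   6 orders of magnitude.  Default: 21 log-spaced points over
#'   `1e-6 ... 1e4`.
#' @return The GCV-best `penalized_fit`, with a `gcv_profile` tibble
#'   (`lambda`, `gcv`, `dof`) attached.
#' @export
select_lambda_gcv <- function(profile, basis,
                              lambda_grid = 10^seq(-6, 4, length.out = 21)) {
  stopifnot(all(lambda_grid > 0))
  if (length(lambda_grid) < 5 ||
      log10(max(lambda_grid) / min(lambda_grid)) < 6) {
    stop_edapeaks(
      "lambda_grid needs >= 5 positive values spanning >= 6 orders of magnitude",
      "edapeaks_parameter_error")
  }
  fits <- purrr::map(sort(lambda_grid), function(l) {
    tryCatch(fit_penalized_spline(profile, basis, l),
             edapeaks_error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  fits <- fits[ok]
  if (length(fits) == 0L) {
    stop_edapeaks("all candidate fits are degenerate", "edapeaks_rank_deficient")
  }
  gcvs <- vapply(fits, `[[`, numeric(1), "gcv")
  if (all(!is.finite(gcvs))) {
    stop_edapeaks("all candidate fits have non-finite GCV",
                  "edapeaks_rank_deficient")
  }
  best <- fits[[which.min(gcvs)]]
  best$gcv_profile <- tibble::tibble(
    lambda = vapply(fits, `[[`, numeric(1), "lambda"),
    gcv = gcvs,
    dof = vapply(fits, `[[`, numeric(1), "dof"))
  best
}

#' Choose the number of interior knots over a candidate ladder
#'
#' Evaluates a ladder of interior-knot counts (capped at a quarter of the
#' sample size), fits each with its GCV-best penalty, and returns the
#' count minimizing GCV, ties broken toward fewer knots.
#'
#' @inheritParams select_lambda_gcv
#' @param candidates Candidate interior-knot counts.  The default ladder
#'   roughly doubles so profiles with sharp phasic events can still be
#'   resolved; once the basis is rich enough the roughness penalty, not
#'   the knot count, controls smoothness.
#' @param order Spline order.
#' @return The winning `penalized_fit`; the per-candidate table is attached
#'   as `$knot_profile` (`n_interior`, `n_basis`, `lambda`, `gcv`).
#' @export
select_n_knots <- function(profile,
                           candidates = c(5L, 9L, 13L, 17L, 21L, 29L, 37L,
                                          53L, 75L, 107L, 149L),
                           order = 4L,
                           lambda_grid = 10^seq(-6, 4, length.out = 21)) {
  n <- nrow(profile)
  if (n < 20L) {
    stop_edapeaks("need at least 20 points for knot-count selection",
                  "edapeaks_too_short")
  }
  candidates <- sort(unique(candidates[candidates <= n / 4]))
  if (length(candidates) == 0L) candidates <- max(1L, floor(n / 4))
  span <- range(profile$elapsed)
  fits <- list()
  kk <- integer(0)
  for (k in candidates) {
    f <- tryCatch(
      select_lambda_gcv(profile, make_equispaced_knots(span, k, order),
                        lambda_grid),
      edapeaks_error = function(e) {
        rlang::warn(sprintf("knot count %d excluded: %s", k,
                            conditionMessage(e)))
        NULL
      })
    if (is.null(f)) next
    fits[[length(fits) + 1L]] <- f
    kk <- c(kk, k)
  }
  if (length(fits) == 0L) {
    stop_edapeaks("no knot-count candidate produced a valid fit",
                  "edapeaks_rank_deficient")
  }
  gcvs <- vapply(fits, `[[`, numeric(1), "gcv")
  best <- fits[[which.min(gcvs)]]  # which.min takes the first = fewest knots
  best$knot_profile <- tibble::tibble(
    n_interior = kk,
    n_basis = kk + as.integer(order),
    lambda = vapply(fits, `[[`, numeric(1), "lambda"),
    gcv = gcvs)
  best
}

#' Evaluate a penalized-spline fit and its derivatives on a grid
#'
#' Returns the spline value and its exact first and second derivatives via
#' the derivative basis expansion (no finite differencing).
#'
#' @param fit A `penalized_fit`.
#' @param grid Evaluation times (seconds), within the basis span.
#' @return An `eda_smooth`: tibble with columns `t`, `value`, `d1` (1/s),
#'   `d2` (1/s^2); `method = "fda"` and the fit stored in the `meta`
#'   attribute.
#' @export
evaluate_fit <- function(fit, grid) {
  stopifnot(inherits(fit, "penalized_fit"))
  b <- fit$basis
  if (min(grid) < b$boundary[1] - 1e-9 || max(grid) > b$boundary[2] + 1e-9) {
    stop_edapeaks("grid extends outside the basis span; extrapolation not supported",
                  "edapeaks_extrapolation")
  }
  grid <- pmin(pmax(grid, b$boundary[1]), b$boundary[2])
  val <- function(d) {
    drop(splines::splineDesign(b$knots, grid, ord = b$order,
                               derivs = rep(d, length(grid))) %*%
           fit$coefficients)
  }
  out <- tibble::tibble(t = grid, value = val(0L), d1 = val(1L), d2 = val(2L))
  new_eda_tbl(out, "eda_smooth",
              meta = list(method = "fda", fit = fit,
                          lambda = fit$lambda, dof = fit$dof, gcv = fit$gcv))
}

#' Penalized B-spline smoothing of a normalized EDA profile
#'
#' One-call driver for the functional-data-analysis smoother: knot-count
#' selection (or a fixed basis size), GCV selection of the roughness
#' penalty, and evaluation of the curve with its first two derivatives on a
#' dense grid for peak detection.
#'
#' @param profile An `eda_profile` from [normalize_eda()].
#' @param n_basis `"auto"` to select the interior-knot count by GCV over a
#'   candidate ladder, or an integer number of basis functions (e.g. 13)
#'   for a fixed equally spaced basis.
#' @param lambda `"auto"` for GCV selection over `lambda_grid`, or a fixed
#'   penalty weight.
#' @param grid_factor Evaluation-grid density as a multiple of the sample
#'   rate (default 10, i.e. 0.025 s steps at 4 Hz), so derivative roots are
#'   well localized.
#' @param order Spline order (4 = cubic).
#' @inheritParams select_lambda_gcv
#' @return An `eda_smooth` tibble (`t`, `value`, `d1`, `d2`) with fit
#'   metadata in the `meta` attribute.
#' @export
#' @examples
#' sim <- eda_scenario("clean", seed = 1)
#' seg <- segment_by_window(sim$recording,
#'                          list(task_id = "task", start = 0, end = 300))
#' prof <- normalize_eda(flag_invalid(seg) |> excise_invalid())
#' sm <- smooth_fda(prof, n_basis = 13)
#' glance(sm)
smooth_fda <- function(profile, n_basis = "auto", lambda = "auto",
                       grid_factor = 10, order = 4L,
                       lambda_grid = 10^seq(-6, 4, length.out = 21)) {
  span <- range(profile$elapsed)
  fit <- if (identical(n_basis, "auto")) {
    if (identical(lambda, "auto")) {
      select_n_knots(profile, order = order, lambda_grid = lambda_grid)
    } else {
      select_n_knots(profile, order = order, lambda_grid = lambda)
    }
  } else {
    basis <- make_equispaced_knots(span, as.integer(n_basis) - order, order)
    if (identical(lambda, "auto")) {
      select_lambda_gcv(profile, basis, lambda_grid)
    } else {
      fit_penalized_spline(profile, basis, lambda)
    }
  }
  sr <- attr(profile, "sample_rate", exact = TRUE) %||%
    (1 / median(diff(profile$elapsed)))
  step <- 1 / (sr * grid_factor)
  grid <- seq(span[1], span[2], by = step)
  if (tail(grid, 1) < span[2]) grid <- c(grid, span[2])
  sm <- evaluate_fit(fit, grid)
  m <- meta_of(sm)
  m$grid_factor <- grid_factor
  m$window <- attr(profile, "window", exact = TRUE)
  attr(sm, "meta") <- m
  sm
}
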