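test_that("plug-in bandwidth lands near the cross-validation optimum", {
  set.seed(1)
  t <- seq(0, 300, length.out = 1200)
  y <- sin(2 * pi * t / 60) + rnorm(1200, 0, 0.2)
  h_pi <- plugin_bandwidth(t, y)
  # exhaustive leave-one-out CV oracle over an h grid
  hs <- exp(seq(log(0.8), log(20), length.out = 20))
  cv <- vapply(hs, function(h) {
    f <- local_poly_fit(t, y, h, degree = 1, grid = t)
    num <- y - f$value
    # recompute leverage directly for the CV shortcut
    lev <- vapply(seq_along(t), function(i) {
      u <- (t - t[i]) / h
      idx <- which(abs(u) < 1)
      dt <- t[idx] - t[i]
      w <- 0.75 * (1 - (dt / h)^2)
      X <- cbind(1, dt)
      M <- solve(crossprod(X, X * w))
      M[1, 1] * w[dt == 0][1]
    }, numeric(1))
    mean((num / (1 - lev))^2)
  }, numeric(1))
  h_cv <- hs[which.min(cv)]
  expect_gt(h_pi, h_cv / 2)
  expect_lt(h_pi, h_cv * 2)

  expect_error(plugin_bandwidth(1:10, rnorm(10)),
               class = "edapeaks_too_short")
})

test_that("noisier data select wider plug-in bandwidths", {
  t <- seq(0, 300, length.out = 1200)
  hits <- 0L
  for (r in 1:50) {
    set.seed(r)
    e <- rnorm(1200)
    h1 <- plugin_bandwidth(t, sin(2 * pi * t / 60) + 0.15 * e)
    h2 <- plugin_bandwidth(t, sin(2 * pi * t / 60) + 0.30 * e)
    if (h2 > h1) hits <- hits + 1L
  }
  expect_gte(hits, 45)
})

test_that("local polynomial fits reproduce polynomials of their degree", {
  set.seed(2)
  t <- sort(runif(200, 0, 10))
  grid <- seq(0.5, 9.5, by = 0.1)
  for (p in 1:3) {
    cf <- rnorm(p + 1)
    y <- drop(outer(t, 0:p, `^`) %*% cf)
    truth <- drop(outer(grid, 0:p, `^`) %*% cf)
    for (h in c(0.8, 2, 5)) {
      f <- local_poly_fit(t, y, h, degree = p, grid = grid)
      expect_lt(max(abs(f$value - truth)), 1e-8)
    }
  }
})

test_that("degree-1 fits are biased at curvature maxima, degree-2 exact", {
  t <- seq(-3, 3, length.out = 301)
  y <- 4 - t^2                      # noiseless parabola, apex at 0
  f2 <- local_poly_fit(t, y, h = 1, degree = 2, grid = 0)
  expect_equal(f2$value, 4, tolerance = 1e-10)
  expect_equal(f2$d2, -2, tolerance = 1e-8)
  f1 <- local_poly_fit(t, y, h = 1, degree = 1, grid = 0)
  expect_lt(f1$value, 4 - 0.01)    # smoothing bias at the apex
})

test_that("kernel windows with too few points widen with a warning", {
  t <- c(seq(0, 1, 0.05), seq(9, 10, 0.05))
  y <- sin(t)
  expect_warning(local_poly_fit(t, y, h = 0.5, degree = 1, grid = 5),
                 class = "edapeaks_window_widened")
})

test_that("the difference-based AR estimator recovers known coefficients", {
  # white noise: the estimate stays within the sampling bound
  set.seed(7)
  eps <- rnorm(2000)
  m <- estimate_ar_difference_based(eps, 1)
  expect_lt(abs(m$beta), 0.07)

  # AR(1), beta = 0.6: accurate on average, agrees with Yule-Walker
  errs <- yw_gap <- numeric(100)
  for (r in 1:100) {
    set.seed(r)
    eps <- sim_ar_series(2000, 0.6)
    b_hat <- estimate_ar_difference_based(eps, 1)$beta
    b_yw <- stats::ar.yw(eps, order.max = 1, aic = FALSE)$ar
    errs[r] <- abs(b_hat - 0.6)
    yw_gap[r] <- abs(b_hat - b_yw)
  }
  expect_lt(mean(errs), 0.1)
  expect_lt(max(yw_gap), 0.05)

  # AR(2)
  errs2 <- t(vapply(1:30, function(r) {
    set.seed(r + 500)
    eps <- sim_ar_series(4000, c(0.5, -0.3))
    abs(estimate_ar_difference_based(eps, 2)$beta - c(0.5, -0.3))
  }, numeric(2)))
  expect_lt(mean(errs2[, 1]), 0.1)
  expect_lt(mean(errs2[, 2]), 0.1)

  expect_error(estimate_ar_difference_based(rnorm(15), 1),
               class = "edapeaks_too_short")
})

test_that("AR estimation error shrinks with the series length", {
  meds <- vapply(c(500, 2000, 8000), function(n) {
    errs <- vapply(1:50, function(r) {
      set.seed(r + n)
      abs(estimate_ar_difference_based(sim_ar_series(n, 0.6), 1)$beta - 0.6)
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(meds) < 0))
})

test_that("BIC selects the right AR order", {
  d_white <- vapply(1:100, function(r) {
    set.seed(r)
    select_ar_order(rnorm(2000), d_max = 8)$order
  }, integer(1))
  expect_gte(mean(d_white == 0), 0.9)

  d_ar1 <- vapply(1:100, function(r) {
    set.seed(r + 200)
    select_ar_order(sim_ar_series(2000, 0.6), d_max = 8)$order
  }, integer(1))
  expect_gte(mean(d_ar1 == 1), 0.8)

  m0 <- select_ar_order(rnorm(500), d_max = 0)
  expect_equal(m0$order, 0L)
  expect_length(m0$beta, 0)
})

test_that("response correction is exact arithmetic on the lags", {
  y <- c(5, 6, 7, 8)
  eps <- c(1, -1, 2, 0)
  ar1 <- structure(list(order = 1L, beta = 0.6, innovation_var = 1,
                        bic = 0, stationary = TRUE), class = "ar_model")
  ystar <- correct_response(y, eps, ar1)
  expect_true(is.na(ystar[1]))
  expect_equal(as.numeric(ystar[2:4]), y[2:4] - 0.6 * eps[1:3])
  expect_equal(attr(ystar, "excluded"), 1L)

  ar0 <- structure(list(order = 0L, beta = numeric(0), innovation_var = 1,
                        bic = 0, stationary = TRUE), class = "ar_model")
  y0 <- correct_response(y, eps, ar0)
  expect_equal(as.numeric(y0), y)
})

test_that("correction whitens the errors around the true curve", {
  hits <- 0L
  for (r in 1:20) {
    set.seed(r)
    t <- seq(0, 150, length.out = 600)
    m_true <- 0.5 + 0.3 * sin(2 * pi * t / 50)
    y <- m_true + sim_ar_series(600, 0.6, sd = 0.05)
    h <- plugin_bandwidth(t, y)
    init <- local_poly_fit(t, y, h, degree = 1, grid = t)
    eps <- y - init$value
    ar <- estimate_ar_difference_based(eps, 1)
    ystar <- correct_response(y, eps, ar)
    keep <- !is.na(ystar)
    if (abs(lag1_acf(ystar[keep] - m_true[keep])) <
        abs(lag1_acf(y - m_true))) hits <- hits + 1L
  }
  expect_gte(hits, 18)
})

test_that("the two-stage AR fit never does worse than the initial fit", {
  set.seed(3)
  t <- seq(0, 300, length.out = 2400)
  m_true <- 0.5 + 0.3 * sin(2 * pi * t / 75)
  y <- m_true + sim_ar_series(2400, 0.6, sd = 0.05)
  prof <- tibble::tibble(elapsed = t, value = y)
  sm <- fit_lpr_ar(prof, grid_factor = 1)
  meta <- attr(sm, "meta")
  init <- local_poly_fit(t, y, meta$h_initial, degree = 1, grid = sm$t)
  truth_on_grid <- 0.5 + 0.3 * sin(2 * pi * sm$t / 75)
  rmse_final <- sqrt(mean((sm$value - truth_on_grid)^2))
  rmse_init <- sqrt(mean((init$value - truth_on_grid)^2))
  expect_lte(rmse_final, rmse_init)
  expect_gte(meta$ar$order, 1L)
})

test_that("independent noise leaves the two-stage fit at the initial fit", {
  set.seed(9)
  t <- seq(0, 150, length.out = 600)
  y <- 0.5 + 0.3 * sin(2 * pi * t / 50) + rnorm(600, 0, 0.05)
  prof <- tibble::tibble(elapsed = t, value = y)
  sm <- fit_lpr_ar(prof, grid_factor = 1)
  init <- local_poly_fit(t, y, attr(sm, "meta")$h_initial, degree = 1,
                         grid = sm$t)
  expect_lt(max(abs(sm$value - init$value)), 0.02)
})

test_that("forcing AR order zero reproduces the plain local fit bitwise", {
  dat <- scenario_profile("clean", seed = 5)
  sm <- fit_lpr_ar(dat$profile, d_max = 0, grid_factor = 2)
  h <- attr(sm, "meta")$h_initial
  plain <- local_poly_fit(dat$profile$elapsed, dat$profile$value, h,
                          degree = 1, grid = sm$t)
  expect_identical(sm$value, plain$value)
  expect_identical(sm$d1, plain$d1)
  expect_identical(sm$d2, plain$d2)
})

test_that("quadratic fits dampen SCR peaks less than linear fits", {
  dat <- scenario_profile("clean", seed = 6)
  prof <- dat$profile
  h <- plugin_bandwidth(prof$elapsed, prof$value)
  apexes <- dat$truth$events$t_apex
  f1 <- local_poly_fit(prof$elapsed, prof$value, h, degree = 1,
                       grid = apexes)
  f2 <- local_poly_fit(prof$elapsed, prof$value, h, degree = 2,
                       grid = apexes)
  expect_true(all(f2$value >= f1$value - 1e-9))
})
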