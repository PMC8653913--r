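test_that("equally spaced knots produce the expected basis size", {
  b <- make_equispaced_knots(c(0, 300), n_interior = 9)
  expect_equal(b$interior, seq(30, 270, by = 30))
  expect_equal(b$n_basis, 13)
  expect_equal(sum(b$knots == 0), 4)
  expect_equal(sum(b$knots == 300), 4)

  expect_equal(make_equispaced_knots(c(0, 10), 1)$interior, 5)
  expect_error(make_equispaced_knots(c(0, 10), 0),
               class = "edapeaks_parameter_error")
  expect_error(make_equispaced_knots(c(10, 0), 3),
               class = "edapeaks_parameter_error")
})

test_that("a huge penalty collapses the fit onto its affine null space", {
  set.seed(2)
  tt <- seq(0, 30, length.out = 200)
  prof <- tibble::tibble(elapsed = tt, value = sin(tt) + rnorm(200, 0, 0.1))
  f <- fit_penalized_spline(prof, make_equispaced_knots(c(0, 30), 9), 1e9)
  sm <- evaluate_fit(f, seq(0, 30, by = 0.01))
  expect_lt(max(abs(sm$d2)), 1e-6)
  # affine means value is a straight line
  resid_line <- residuals(lm(sm$value ~ sm$t))
  expect_lt(max(abs(resid_line)), 1e-4)
})

test_that("an unpenalized saturated basis interpolates the data", {
  set.seed(3)
  tt <- seq(0, 10, length.out = 13)
  prof <- tibble::tibble(elapsed = tt, value = rnorm(13))
  b <- make_equispaced_knots(c(0, 10), 13 - 4)  # n_basis == n
  f <- fit_penalized_spline(prof, b, 0)
  expect_lt(max(abs(f$residuals)), 1e-8)
})

test_that("data that are exactly a spline are recovered at lambda = 0", {
  set.seed(4)
  b <- make_equispaced_knots(c(0, 10), 9)
  cf <- rnorm(b$n_basis)
  tt <- seq(0, 10, length.out = 80)
  y <- drop(splines::splineDesign(b$knots, tt, ord = 4) %*% cf)
  f <- fit_penalized_spline(tibble::tibble(elapsed = tt, value = y), b, 0)
  expect_lt(max(abs(f$coefficients - cf)), 1e-8)
  expect_lt(max(abs(f$fitted - y)), 1e-8)
})

test_that("evaluated derivatives are the exact spline derivatives", {
  dat <- scenario_profile("clean", seed = 2)
  f <- select_lambda_gcv(dat$profile,
                         make_equispaced_knots(c(0, 299.75), 21))
  grid <- seq(0.5, 299, by = 0.01)
  sm <- evaluate_fit(f, grid)
  # fitted values at the data times reproduce y - residuals exactly
  at_data <- evaluate_fit(f, f$x)
  expect_lt(max(abs(at_data$value - (f$y - f$residuals))), 1e-10)
  # d1 against central finite differences of value
  fd1 <- (sm$value[3:nrow(sm)] - sm$value[1:(nrow(sm) - 2)]) / 0.02
  expect_lt(max(abs(sm$d1[2:(nrow(sm) - 1)] - fd1)), 1e-4)
  # d2 against finite differences of d1
  fd2 <- (sm$d1[3:nrow(sm)] - sm$d1[1:(nrow(sm) - 2)]) / 0.02
  expect_lt(max(abs(sm$d2[2:(nrow(sm) - 1)] - fd2)), 1e-3)
  expect_error(evaluate_fit(f, seq(-5, 10, 1)),
               class = "edapeaks_extrapolation")
})

test_that("effective dof is non-increasing in the penalty", {
  set.seed(5)
  tt <- seq(0, 60, length.out = 240)
  prof <- tibble::tibble(elapsed = tt,
                         value = sin(2 * pi * tt / 20) + rnorm(240, 0, 0.2))
  b <- make_equispaced_knots(c(0, 60), 13)
  dofs <- vapply(10^seq(-6, 6, length.out = 13), function(l)
    fit_penalized_spline(prof, b, l)$dof, numeric(1))
  expect_true(all(diff(dofs) <= 1e-8))
  expect_gt(dofs[1], dofs[13])
})

test_that("GCV picks heavier penalties for noisier data", {
  tt <- seq(0, 30, length.out = 150)
  b <- make_equispaced_knots(c(0, 30), 5)
  hits <- 0L
  for (r in 1:50) {
    set.seed(r)
    e <- rnorm(150)
    l_lo <- select_lambda_gcv(
      tibble::tibble(elapsed = tt, value = sin(2 * pi * tt / 15) + 0.05 * e),
      b)$lambda
    l_hi <- select_lambda_gcv(
      tibble::tibble(elapsed = tt, value = sin(2 * pi * tt / 15) + 0.5 * e),
      b)$lambda
    if (l_hi > l_lo) hits <- hits + 1L
  }
  expect_gte(hits, 45)
})

test_that("GCV keeps a constant-plus-noise fit near the null-space dof", {
  dofs <- vapply(1:15, function(r) {
    set.seed(r)
    p <- tibble::tibble(elapsed = seq(0, 60, length.out = 200),
                        value = 1 + rnorm(200, 0, 0.1))
    select_lambda_gcv(p, make_equispaced_knots(c(0, 60), 9))$dof
  }, numeric(1))
  expect_lte(median(dofs), 2.5)
})

test_that("knot-count selection resolves structure but prefers parsimony", {
  # two-bump signal: the chosen count must resolve both bumps
  set.seed(6)
  tt <- seq(0, 60, length.out = 300)
  truth <- exp(-(tt - 18)^2 / 18) + 0.8 * exp(-(tt - 42)^2 / 18)
  prof <- tibble::tibble(elapsed = tt, value = truth + rnorm(300, 0, 0.05))
  f <- select_n_knots(prof, candidates = c(5L, 9L, 13L, 17L, 21L))
  sm <- evaluate_fit(f, tt)
  expect_lt(sqrt(mean((sm$value - truth)^2)), 2 * 0.05)

  # pure noise: the smallest candidate wins most often, never by less
  # than a clear majority, and the median choice is the smallest
  ks <- vapply(1:50, function(r) {
    set.seed(r + 100)
    p <- tibble::tibble(elapsed = seq(0, 60, length.out = 150),
                        value = 1 + rnorm(150, 0, 0.1))
    length(select_n_knots(p, candidates = c(5L, 9L, 13L, 17L, 21L))$basis$interior)
  }, numeric(1))
  expect_equal(unname(sort(table(ks), decreasing = TRUE))[1],
               sum(ks == 5))
  expect_equal(median(ks), 5)

  # replication mode: a fixed basis size bypasses selection
  dat <- scenario_profile("clean", seed = 3)
  sm13 <- smooth_fda(dat$profile, n_basis = 13)
  expect_equal(attr(sm13, "meta")$fit$basis$n_basis, 13)
})

test_that("missing or unequally spaced samples are smoothed over", {
  dat <- scenario_profile("clean", seed = 7)
  prof <- dat$profile
  sm_full <- smooth_fda(prof, n_basis = 41)
  set.seed(8)
  drop_idx <- sample(nrow(prof), round(0.1 * nrow(prof)))
  prof_holey <- prof[-drop_idx, ]
  attr(prof_holey, "sample_rate") <- attr(prof, "sample_rate")
  sm_holey <- smooth_fda(prof_holey, n_basis = 41)
  common <- seq(1, 299, by = 0.25)
  v1 <- approx(sm_full$t, sm_full$value, common)$y
  v2 <- approx(sm_holey$t, sm_holey$value, common)$y
  expect_lt(sqrt(mean((v1 - v2)^2)), 0.05 * diff(range(v1)))
})

test_that("rank-deficient designs fail loudly, naming the empty span", {
  tt <- c(seq(0, 2, 0.1), seq(8, 10, 0.1))
  prof <- tibble::tibble(elapsed = tt, value = sin(tt))
  b <- make_equispaced_knots(c(0, 10), 9)
  expect_error(fit_penalized_spline(prof, b, 0),
               class = "edapeaks_rank_deficient")
})
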