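# Fixtures are built in code; oracles here are deliberately independent of
# the implementation paths they check.

# a smoothed-profile object from closed-form value/d1/d2 functions
profile_from_fn <- function(grid, f, f1, f2) {
  out <- tibble::tibble(t = grid, value = f(grid), d1 = f1(grid),
                        d2 = f2(grid))
  attr(out, "meta") <- list(method = "fda")
  class(out) <- c("eda_smooth", class(out))
  out
}

# random smooth profile: sum of Gaussian bumps with analytic derivatives
random_smooth_profile <- function(seed, span = 60, step = 0.05,
                                  n_bumps = NULL) {
  set.seed(seed)
  k <- n_bumps %||% sample(2:6, 1)
  a <- runif(k, 0.2, 1)
  ctr <- runif(k, 0.05 * span, 0.95 * span)
  w <- runif(k, 1.5, 6)
  f <- function(t) rowSums(vapply(seq_len(k), function(i)
    a[i] * exp(-(t - ctr[i])^2 / (2 * w[i]^2)), numeric(length(t))))
  f1 <- function(t) rowSums(vapply(seq_len(k), function(i)
    a[i] * exp(-(t - ctr[i])^2 / (2 * w[i]^2)) *
      (-(t - ctr[i]) / w[i]^2), numeric(length(t))))
  f2 <- function(t) rowSums(vapply(seq_len(k), function(i)
    a[i] * exp(-(t - ctr[i])^2 / (2 * w[i]^2)) *
      (((t - ctr[i])^2 / w[i]^2 - 1) / w[i]^2), numeric(length(t))))
  profile_from_fn(seq(0, span, by = step), f, f1, f2)
}

# brute-force discrete-scan peak detector: local maxima/minima as grid
# points above/below both neighbours, then the same nearest-minimum /
# both-drops / right-limit rule as the detector's documented contract
brute_force_peaks <- function(profile, threshold = 0.1) {
  v <- profile$value
  t <- profile$t
  n <- length(v)
  i <- 2:(n - 1)
  is_max <- c(FALSE, v[i] > v[i - 1] & v[i] > v[i + 1], FALSE)
  is_min <- c(FALSE, v[i] < v[i - 1] & v[i] < v[i + 1], FALSE)
  maxima <- which(is_max)
  minima <- which(is_min)
  kept <- numeric(0)
  for (m in maxima) {
    right <- minima[minima > m]
    if (length(right) == 0) next            # incomplete at the right limit
    left <- minima[minima < m]
    lval <- if (length(left)) v[left[length(left)]] else v[1]
    drop_l <- v[m] - lval
    drop_r <- v[m] - v[right[1]]
    if (drop_l > threshold && drop_r > threshold) kept <- c(kept, t[m])
  }
  kept
}

# standard normalized profile from a packaged scenario
scenario_profile <- function(name = "clean", seed = 1, filter = FALSE) {
  sim <- eda_scenario(name, seed = seed)
  seg <- segment_by_window(sim$recording,
                           list(task_id = name, start = 0, end = 300))
  if (filter) {
    seg <- apply_fir(seg, design_fir_lowpass(4))
  }
  prof <- normalize_eda(excise_invalid(flag_invalid(seg)),
                        source = if (filter) "filtered" else "raw")
  list(profile = prof, truth = sim$truth)
}

# AR(p) series with standard-normal innovations (independent oracle input)
sim_ar_series <- function(n, beta, sd = 1, burn = 100) {
  innov <- stats::rnorm(n + burn, 0, sd)
  x <- if (length(beta)) {
    as.numeric(stats::filter(innov, beta, method = "recursive"))
  } else innov
  x[(burn + 1):(n + burn)]
}

lag1_acf <- function(x) {
  x <- x[is.finite(x)]
  stats::cor(x[-1], x[-length(x)])
}
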