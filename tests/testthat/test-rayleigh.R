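test_that("a noiseless Rayleigh series is recovered exactly", {
  s <- exact_series(c(1, 0.8, 0.5, 0.19), eps_C = -2.4)
  fit <- fit_rayleigh(s, "C")
  expect_equal(fit$epsilon_bulk, -2.4, tolerance = 1e-11)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$n_points, 4L)

  # hydrogen leg of the same series
  fitH <- fit_rayleigh(s, "H")
  expect_equal(fitH$epsilon_bulk, -57, tolerance = 1e-9)
})

test_that("exact-model recovery holds across random designs (linearization is exact)", {
  set.seed(42)
  for (i in 1:40) {
    eps <- stats::runif(1, -100, -0.1)
    d0 <- stats::runif(1, -300, 100)
    nf <- sample(3:9, 1)
    f <- sort(stats::runif(nf, 0.05, 0.999), decreasing = TRUE)
    f <- c(1, f)
    s <- isotope_series(
      time = (seq_along(f) - 1) * 10, conc = 50 * f, compound = "benzene",
      delta13C = exact_rayleigh_delta(f, eps, d0)
    )
    fit <- fit_rayleigh(s, "C")
    expect_lt(abs(fit$epsilon_bulk - eps), 1e-9)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("two points with forced origin solve the closed-form Rayleigh slope", {
  d_half <- exact_rayleigh_delta(0.5, -2.4, -25.2) # ~ -23.577 permil
  s <- isotope_series(
    time = c(0, 30), conc = c(12, 6), compound = "benzene",
    delta13C = c(-25.2, d_half)
  )
  expect_error(fit_rayleigh(s, "C"), "fit_rayleigh",
    class = "csiaray_precondition_error") # free intercept needs 3
  fit <- fit_rayleigh(s, "C", forced_origin = TRUE)
  # closed-form two-point oracle: eps = 1000 * ln(R1/R0) / ln(f1)
  expect_equal(fit$epsilon_bulk, 1000 * log(ratio_factor(d_half, -25.2)) / log(0.5),
    tolerance = 1e-12)
  expect_equal(fit$epsilon_bulk, -2.4, tolerance = 1e-9)
})

test_that("constant deltas with varying f give epsilon = 0", {
  s <- isotope_series(
    time = c(0, 10, 20, 30), conc = c(10, 7, 4, 2), compound = "benzene",
    delta13C = rep(-25.2, 4)
  )
  expect_equal(fit_rayleigh(s, "C")$epsilon_bulk, 0)
})

test_that("the OLS slope matches a closed-form least-squares oracle", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    f <- c(1, sort(stats::runif(n - 1, 0.1, 0.99), decreasing = TRUE))
    d <- exact_rayleigh_delta(f, -3.1, -25.2) + stats::rnorm(n, 0, 0.3)
    d[1] <- -25.2
    s <- isotope_series(time = (1:n - 1) * 5, conc = 20 * f, compound = "benzene",
      delta13C = d)
    for (forced in c(FALSE, TRUE)) {
      fit <- fit_rayleigh(s, "C", forced_origin = forced)
      x <- log(f)
      y <- log(ratio_factor(d, d[1]))
      expect_lt(abs(fit$epsilon_bulk / 1000 - ols_slope_oracle(x, y, forced)), 1e-10)
    }
  }
})

test_that("fit_rayleigh rejects degenerate inputs", {
  s0 <- isotope_series(time = c(0, 10, 20), conc = c(10, 5, 0), compound = "benzene",
    delta13C = c(-25, -24, -23))
  expect_error(fit_rayleigh(s0, "C"), class = "csiaray_domain_error") # C_t = 0
  s1 <- isotope_series(time = c(0, 10, 20), conc = c(10, 10, 10), compound = "benzene",
    delta13C = c(-25, -24, -23))
  expect_error(fit_rayleigh(s1, "C"), class = "csiaray_precondition_error") # var(ln f) = 0
  s2 <- isotope_series(time = c(0, 10, 20), conc = c(10, 5, 2), compound = "benzene")
  expect_error(fit_rayleigh(s2, "C"), class = "csiaray_input_error") # no deltas at all
})

test_that("the 95% CI covers the true enrichment factor at near-nominal rate", {
  hits <- vapply(1:200, function(i) {
    s <- simulate_rayleigh_series(f_grid_10, sigma_delta2H = 0, seed = 5000 + i)
    fit <- fit_rayleigh(s, "C")
    abs(fit$epsilon_bulk - (-2.4)) <= fit$ci95_half_width
  }, logical(1))
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.99)
})

test_that("position parameters scale bulk to reactive-position enrichment factors", {
  expect_error(position_params(z = 7, x_reactive = 6), class = "csiaray_input_error")
  expect_error(position_params(z = 0), class = "csiaray_input_error")

  # benzene is fully symmetric: the correction is the identity
  expect_equal(epsilon_reactive_position(-2.4, position_params()), -2.4)
  # toluene-like case: 7 carbons, 1 reactive
  expect_equal(epsilon_reactive_position(-1.0, position_params(z = 1, n_total = 7,
    x_reactive = 1)), -7.0)
  expect_equal(epsilon_reactive_position(-3.3, position_params(z = 2, n_total = 5,
    x_reactive = 5)), -3.3)
})

test_that("AKIE follows 1/(1 + z * eps_rp/1000) with a transformed CI", {
  expect_equal(round(akie(-2.4)$akie, 4), 1.0146)
  expect_equal(akie(0)$akie, 1)
  expect_equal(akie(-57)$akie, 1 / (1 - 6 * 57 / 1000), tolerance = 1e-12)

  # strictly decreasing in eps_rp; > 1 exactly when eps_rp < 0
  eps <- seq(-100, 50, by = 10)
  vals <- vapply(eps, function(e) akie(e)$akie, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_true(all((vals > 1) == (eps < 0)))

  expect_error(akie(-200), class = "csiaray_domain_error") # denominator <= 0

  # CI endpoints transformed through the same map; asymmetric, larger half
  res <- akie(-2.4, ci95_half_width = 0.3)
  lo <- 1 / (1 + 6 * (-2.7) / 1000)
  hi <- 1 / (1 + 6 * (-2.1) / 1000)
  expect_equal(res$ci_bounds, sort(c(lo, hi)), tolerance = 1e-12)
  expect_equal(res$ci95_half_width, max(abs(c(lo, hi) - res$akie)), tolerance = 1e-12)
})
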