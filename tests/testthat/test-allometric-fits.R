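test_that("noise-free power laws are recovered exactly by both methods", {
  d <- c(5, 10, 20, 40)
  for (m in c("RMA", "OLS")) {
    f <- fit_power_law(d, 10 * d^2, method = m)
    expect_equal(f$exponent, 2, tolerance = 1e-10)
    expect_equal(f$log10_constant, 1, tolerance = 1e-10)
    expect_equal(f$r2, 1, tolerance = 1e-10)
  }
})

test_that("RMA and OLS slopes match the hand-computed sd-ratio oracle", {
  x <- c(0, 1, 2, 3)
  y <- c(0.1, 1.9, 4.1, 5.9)
  f_rma <- fit_power_law(10^x, 10^y, method = "RMA")
  f_ols <- fit_power_law(10^x, 10^y, method = "OLS")
  # sd(y) = sqrt(19.24/3), sd(x) = sqrt(5/3), Sxy/Sxx = 9.8/5
  expect_equal(f_rma$exponent, sqrt(19.24 / 5), tolerance = 1e-10)
  expect_equal(f_rma$exponent, 1.962, tolerance = 1e-3)
  expect_equal(f_ols$exponent, 1.96, tolerance = 1e-10)
  r <- 9.8 / sqrt(5 * 19.24)
  expect_equal(f_rma$exponent, f_ols$exponent / abs(r), tolerance = 1e-10)
  expect_equal(f_rma$exponent, rma_slope_oracle(x, y), tolerance = 1e-12)
})

test_that("RMA is symmetric: swapping the variables gives the reciprocal slope", {
  set.seed(3)
  d <- 10^rnorm(30, 1, 0.15)
  v <- 10^(-0.9 + 2.7 * log10(d) + rnorm(30, 0, 0.05))
  f_dv <- fit_power_law(v, d, method = "RMA")   # D vs V
  f_vd <- fit_power_law(d, v, method = "RMA")   # V vs D
  expect_equal(f_dv$exponent, 1 / f_vd$exponent, tolerance = 1e-12)
})

test_that("RMA slope magnitude >= OLS slope magnitude, with equality iff |r| = 1", {
  set.seed(4)
  for (i in 1:20) {
    g <- make_log_site(25, runif(1, -2, 2), noise_sd = runif(1, 0.01, 0.2))
    f_rma <- fit_power_law(10^g$x, 10^g$y, method = "RMA")
    f_ols <- fit_power_law(10^g$x, 10^g$y, method = "OLS")
    expect_gte(abs(f_rma$exponent), abs(f_ols$exponent) - 1e-12)
    expect_equal(abs(f_rma$exponent), abs(f_ols$exponent) / sqrt(f_ols$r2),
                 tolerance = 1e-10)
  }
})

test_that("the RMA slope CI shrinks as n grows at fixed r2", {
  x <- c(1, 2, 3, 4)
  y <- 2 * x + c(0.1, -0.1, -0.1, 0.1)
  widths <- sapply(c(1, 4, 16), function(m) {
    f <- fit_power_law(10^rep(x, m), 10^rep(y, m), method = "RMA")
    f$ci_high - f$ci_low
  })
  expect_true(all(diff(widths) < 0))
})

test_that("degenerate and invalid inputs are rejected", {
  expect_error(fit_power_law(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_power_law(c(1, 2, -3), c(1, 2, 3)), "positive")
  expect_error(fit_power_law(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_error(fit_power_law(c(1, 2, 3), c(2, 2, 2)), "degenerate")
})

test_that("per-site relation fits carry the z' = x * y' sd-ratio identity", {
  st <- generate_study(n_dev = 3, n_test = 3, n_trees = 20, seed = 5)
  fits <- fit_site_relations(st$trees, method = "RMA")
  x <- fits[fits$relation == "H_vs_D", "exponent"]
  y <- fits[fits$relation == "D_vs_V", "exponent"]
  z <- fits[fits$relation == "H_vs_V", "exponent"]
  expect_equal(z, x * y, tolerance = 1e-12)
  expect_equal(nrow(fits), 6 * 4)
  expect_true(all(fits$ci_low <= fits$exponent & fits$exponent <= fits$ci_high))
})

test_that("low site sizes are flagged", {
  st <- generate_study(n_dev = 3, n_test = 3, n_trees = c(5, 10, 10, 10, 10, 10),
                       seed = 6)
  fits <- fit_site_relations(st$trees, method = "RMA", relations = "H_vs_D")
  expect_equal(fits$low_n, st$sites$n_trees < 6)
})

test_that("common-slope test accepts homogeneous and flags heterogeneous slopes", {
  # identical noise-free lines: no heterogeneity evidence at all
  x <- c(0, 0.5, 1, 1.5)
  g0 <- list(list(x = x, y = 2 * x + 1), list(x = x, y = 2 * x - 1))
  st0 <- common_slope_test(g0)
  expect_equal(st0$statistic, 0, tolerance = 1e-8)
  expect_equal(st0$p_value, 1, tolerance = 1e-6)

  set.seed(8)
  g1 <- list(make_log_site(60, 0.7), make_log_site(60, 1.3))
  st1 <- common_slope_test(g1)
  expect_lt(st1$p_value, 0.001)
  expect_equal(st1$df, 1)
  expect_error(common_slope_test(g1[1]), "2 groups")
})
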