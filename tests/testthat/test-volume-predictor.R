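make_dev_fits <- function(alpha, log_beta) {
  data.frame(site_id = sprintf("S%02d", seq_along(alpha)),
             exponent = alpha, log10_constant = log_beta,
             stringsAsFactors = FALSE)
}

test_that("calibration recovers a collinear constant-exponent law exactly", {
  a <- c(2.4, 2.6, 2.8, 3.0)
  m <- calibrate_volume_model(make_dev_fits(a, -1.5 * a + 0.2), phi = 1.1)
  expect_equal(m$c, -1.5, tolerance = 1e-10)
  expect_equal(m$d, 0.2, tolerance = 1e-10)
  expect_equal(m$r2, 1, tolerance = 1e-10)
  expect_equal(m$phi, 1.1)
})

test_that("degenerate calibration inputs are rejected", {
  expect_error(calibrate_volume_model(make_dev_fits(rep(2.7, 5), rep(-3.9, 5)), 1.1),
               "degenerate")
  expect_error(calibrate_volume_model(make_dev_fits(c(2.4, 2.6), c(0, 1)), 1.1),
               "3 development sites")
  expect_error(calibrate_volume_model(make_dev_fits(2:4 / 1, c(0, 1, 2)), -1),
               "positive")
})

test_that("the implied V-vs-D exponent follows the covariation curve", {
  expect_equal(site_exponent_from_hd(1, 1), 3)
  expect_equal(site_exponent_from_hd(1, 1.1), 2.727273, tolerance = 1e-6)
  set.seed(20)
  x <- runif(20, 0.5, 2)
  phi <- runif(20, 0.8, 1.4)
  expect_equal(site_exponent_from_hd(x, phi),
               1 / covariation_predict(phi, x)$y, tolerance = 1e-14)
  expect_error(site_exponent_from_hd(-1, 1), "positive")
})

test_that("predicted volume is pure power-law arithmetic and monotone in D", {
  m <- structure(list(phi = 1, c = 0, d = log10(2e-4), r2 = 1,
                      calibration_sites = c("a", "b", "c")),
                 class = "volume_model")
  # alpha = 3, so V = 2e-4 * D^3
  expect_equal(predict_volume(m, 1, 10), 2e-4 * 1000, tolerance = 1e-12)
  d <- seq(2, 60, by = 0.5)
  expect_true(all(diff(predict_volume(m, 1, d)) > 0))
  expect_error(predict_volume(m, 1, -5), "positive")
})

test_that("on noise-free sites the chain reproduces each site's own fit exactly", {
  st <- generate_study(n_dev = 4, n_test = 4, n_trees = 25, noise_sd = 0,
                       seed = 21)
  ols <- fit_site_relations(st$trees, method = "OLS")
  rma <- fit_site_relations(st$trees, method = "RMA")
  x <- rma[rma$relation == "H_vs_D", "exponent"]
  y <- rma[rma$relation == "D_vs_V", "exponent"]
  phi <- fit_phi(x = x, y = y, curve_form = "C1")$phi
  expect_equal(phi, st$phi_true, tolerance = 1e-10)
  dev_vd <- ols[ols$relation == "V_vs_D" & ols$site_id %in% st$dev_sites, ]
  m <- calibrate_volume_model(dev_vd, phi)
  # noise-free: every site (dev or test) is predicted exactly
  for (sid in c(st$dev_sites, st$test_sites)) {
    d <- st$trees[st$trees$site_id == sid, ]
    x_site <- ols[ols$relation == "H_vs_D" & ols$site_id == sid, "exponent"]
    expect_equal(predict_volume(m, x_site, d$dbh_cm), d$volume_m3,
                 tolerance = 1e-8)
  }
})

test_that("calibrated (c, d) recover the generator's constant-exponent law", {
  # truth from the shared-pivot construction: log beta_V = d* + c* alpha
  st0 <- generate_study(n_dev = 6, n_test = 6, n_trees = 10, noise_sd = 0, seed = 1)
  tr <- st0$sites
  truth <- lm(log_betaV_true ~ alpha_VD_true, data = tr)
  c_star <- unname(coef(truth)[2])
  d_star <- unname(coef(truth)[1])
  set.seed(22)
  ok <- replicate(40, {
    seed <- sample.int(1e6, 1)
    st <- generate_study(n_dev = 12, n_test = 3, n_trees = 50, noise_sd = 0.02,
                         seed = seed)
    ols <- fit_site_relations(st$trees, method = "OLS",
                              relations = c("V_vs_D", "H_vs_D", "D_vs_V"))
    rma <- fit_site_relations(st$trees, method = "RMA",
                              relations = c("H_vs_D", "D_vs_V"))
    dev <- function(f) f[f$site_id %in% st$dev_sites, ]
    phi <- fit_phi(x = dev(rma[rma$relation == "H_vs_D", ])$exponent,
                   y = dev(rma[rma$relation == "D_vs_V", ])$exponent,
                   curve_form = "C1")$phi
    m <- calibrate_volume_model(dev(ols[ols$relation == "V_vs_D", ]), phi)
    abs(m$c - c_star) < 0.1 && abs(m$d - d_star) < 0.3
  })
  expect_gte(mean(ok), 0.9)
})

test_that("volume models round-trip through the flat text format", {
  m <- calibrate_volume_model(
    make_dev_fits(c(2.4, 2.6, 2.9), c(-0.1, 0.15, 0.42)), phi = 1.07)
  path <- withr::local_tempfile(fileext = ".txt")
  write_volume_model(m, path)
  m2 <- read_volume_model(path)
  expect_identical(m2$phi, m$phi)
  expect_identical(m2$c, m$c)
  expect_identical(m2$d, m$d)
  expect_identical(m2$calibration_sites, m$calibration_sites)
})
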