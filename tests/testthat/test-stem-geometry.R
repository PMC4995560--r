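test_that("frustum volume matches the closed form, its limits and the taper integral", {
  # cylinder limit
  expect_equal(frustum_volume(20, 20, 1), pi * 0.1^2 * 1, tolerance = 1e-12)
  expect_equal(frustum_volume(20, 20, 1), 0.031416, tolerance = 1e-5)
  # zero-length section
  expect_equal(frustum_volume(20, 10, 0), 0)
  # symmetric in the two diameters
  expect_equal(frustum_volume(20, 10, 1), frustum_volume(10, 20, 1))
  # against numerical integration of the linear taper, several shapes
  for (d in list(c(20, 10), c(35, 0), c(8, 7.5), c(0, 12))) {
    expect_equal(frustum_volume(d[1], d[2], 2.3),
                 taper_integral_oracle(d[1], d[2], 2.3), tolerance = 1e-9)
  }
  expect_equal(frustum_volume(20, 10, 1), 0.018326, tolerance = 1e-4)
  expect_error(frustum_volume(-1, 10, 1), "non-negative")
  expect_error(frustum_volume(10, 10, -1), "non-negative")
})

test_that("frustum volume is bounded by the end-diameter cylinders", {
  set.seed(11)
  for (i in 1:50) {
    d <- sort(runif(2, 0.5, 60))
    L <- runif(1, 0.1, 3)
    v <- frustum_volume(d[1], d[2], L)
    expect_gte(v, frustum_volume(d[1], d[1], L))
    expect_lte(v, frustum_volume(d[2], d[2], L))
  }
})

test_that("disc heights follow the felling protocol", {
  expect_equal(measurement_heights(9), c(0.5, 1.3, 2.3, 3.3, 4.3, 5.3, 6.3, 7.3, 8.3))
  expect_equal(measurement_heights(12), c(1.3, 3.3, 5.3, 7.3, 9.3, 11.3))
  expect_equal(measurement_heights(1.5), c(0.5, 1.3))
  expect_equal(measurement_heights(10), c(1.3, 3.3, 5.3, 7.3, 9.3))
  expect_error(measurement_heights(1.3), "1.3")
  # always strictly increasing and strictly below the tip
  for (H in c(1.9, 5.27, 9.99, 10.01, 23.4)) {
    h <- measurement_heights(H)
    expect_true(all(diff(h) > 0))
    expect_lt(max(h), H)
  }
})

test_that("stem profiles validate their invariants", {
  expect_error(stem_profile("t", 10, c(1.3, 1.3), c(10, 9)), "strictly increasing")
  expect_error(stem_profile("t", 10, c(1.3, 11), c(10, 9)), "total height")
  expect_error(stem_profile("t", 10, c(1.3, 5), c(10, 0)), "positive")
  expect_warning(stem_profile("t", 10, c(0.5, 1.3, 5), c(9, 10, 8)), "taper")
})

test_that("total stem volume sums cylinder/frustum sections", {
  p <- stem_profile("t1", 2, c(1, 2), c(10, 10))
  res <- total_stem_volume(p)
  # ground cylinder + middle cylinder + zero-length tip
  expect_equal(res$volume_m3, 2 * pi * 0.05^2, tolerance = 1e-12)
  expect_equal(res$volume_m3, sum(res$sections$volume_m3))
  expect_true(all(res$sections$upper_height_m > res$sections$lower_height_m))

  expect_error(total_stem_volume(stem_profile("t", 5, 1.3, 10)), "2 discs")
})

test_that("dense discs on a cone converge to the analytic cone volume", {
  H <- 8
  d_base <- 30
  h <- seq(0, H - 0.1, by = 0.1)
  p <- stem_profile("cone", H, h[-1], d_base * (1 - h[-1] / H))
  v_exact <- pi * (d_base / 100)^2 * H / 12
  expect_equal(total_stem_volume(p)$volume_m3, v_exact, tolerance = 0.01)
})

test_that("inserting a disc on the linear taper between two discs changes nothing", {
  p1 <- stem_profile("a", 12, c(1.3, 3.3, 5.3), c(20, 16, 10))
  p2 <- stem_profile("a", 12, c(1.3, 2.3, 3.3, 5.3), c(20, 18, 16, 10))
  expect_equal(total_stem_volume(p1)$volume_m3, total_stem_volume(p2)$volume_m3,
               tolerance = 1e-12)
})

test_that("base and tip rules are configurable", {
  p <- stem_profile("b", 12, c(1.3, 3.3), c(20, 16))
  v_cyl <- total_stem_volume(p)$volume_m3
  v_fru <- total_stem_volume(p, base_rule = "frustum")$volume_m3
  expect_gt(v_fru, v_cyl)  # extrapolated butt diameter (22.6 cm) exceeds 20 cm
  v_tip <- total_stem_volume(p, tip_diameter_cm = 5)$volume_m3
  expect_gt(v_tip, v_cyl)
  expect_equal(total_stem_volume(p, base_rule = "frustum")$sections$rule[1], "frustum")
})
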