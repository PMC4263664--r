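test_that("perpendicular distances match analytic gaps and the oracle", {
  circ <- contour(circle_points(c(60, 60), 50, 180))
  expect_equal(average_perpendicular_distance(circ, circ), 0, tolerance = 1e-9)

  inner <- contour(circle_points(c(60, 60), 50, 180))
  outer <- contour(circle_points(c(60, 60), 52, 180))
  expect_equal(average_perpendicular_distance(inner, outer, 1), 2, tolerance = 0.05)

  sq <- contour(c(0, 10, 10, 0), c(0, 0, 10, 10))
  sq2 <- contour(c(0, 10, 10, 0) + 1, c(0, 0, 10, 10))
  got <- average_perpendicular_distance(sq, sq2, 1.5)
  expect_equal(got, apd_oracle(sq, sq2, 1.5), tolerance = 1e-9)
})

test_that("good-contour rule uses a strict 5 mm cut and pools correctly", {
  expect_equal(percent_good(c(2, 6, 3)), 200 / 3, tolerance = 1e-9)
  expect_equal(percent_good(c(5, 5, 5)), 0)     # exactly 5 mm is not good
  expect_equal(percent_good(c(1, 1)), 100)
  expect_equal(percent_good(c(2, 6, 3)), percent_good(c(6, 3, 2)))
  expect_error(percent_good(numeric(0)), "no contour")

  a <- contour(circle_points(c(30, 30), 10, 90))
  b <- contour(circle_points(c(30, 30), 10, 90))
  expect_true(good_contour(a, b, 1))
})

test_that("dice handles the printed toy cases and is symmetric", {
  m <- matrix(FALSE, 10, 10)
  a <- m; a[2:3, 2:3] <- TRUE
  expect_equal(dice(a, a), 1.0)
  b <- m; b[2:3, 3:4] <- TRUE          # 2x2 squares overlapping in 2 px
  expect_equal(dice(a, b), 0.5)
  c2 <- m; c2[8:9, 8:9] <- TRUE
  expect_equal(dice(a, c2), 0.0)
  expect_equal(dice(a, b), dice(b, a))
  expect_error(dice(m, m), "empty")

  set.seed(61)
  for (i in 1:5) {
    a2 <- lvseg:::disc_mask(c(40, 40), c(20 + i, 20), 8 + i)
    b2 <- lvseg:::disc_mask(c(40, 40), c(20, 20 + i), 10)
    d <- dice(a2, b2)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, dice(b2, a2))
  }
})

test_that("volumes follow slice summation and scale with spacing", {
  circ <- contour(circle_points(c(64, 64), 20, 360))
  v <- cavity_volume(list(circ), c(1, 1), 8)
  expect_lt(abs(v - pi * 400 * 8 / 1000) / (pi * 400 * 8 / 1000), 0.02)
  expect_equal(cavity_volume(list(circ, circ), c(1, 1), 8), 2 * v, tolerance = 1e-12)
  expect_equal(cavity_volume(list(circ), c(1, 1), 16), 2 * v, tolerance = 1e-12)
  expect_error(cavity_volume(list(circ), NULL, 8), "spacing")

  # phantom stack: within 3% of the closed-form disc-summation volume
  ph <- generate_phantom_study(phantom_spec(phases = c("ED", "ES")))
  tr <- ph$truth[ph$truth$phase == "ED", ]
  v_endo <- cavity_volume(tr$endo, ph$spec$pixel_spacing_mm, ph$spec$slice_spacing_mm)
  expect_lt(abs(v_endo - ph$analytic_volumes$endo_ED) / ph$analytic_volumes$endo_ED,
            0.03)
})

test_that("ejection fraction and mass follow their defining formulas", {
  expect_equal(ejection_fraction(volume_set(120, 200, 60)), 50)
  expect_equal(ejection_fraction(volume_set(100, 150, 100)), 0)
  expect_equal(ejection_fraction(volume_set(100, 150, 35)), 65)
  expect_error(ejection_fraction(list(endo_ED = 0, endo_ES = 0)), "positive")

  expect_equal(lv_mass(volume_set(100, 200, 50)), 105)
  expect_equal(lv_mass(volume_set(100, 100, 50)), 0)
  expect_equal(lv_mass(volume_set(100, 214.57, 50), density_g_per_mL = 1), 114.57)
  expect_error(volume_set(100, 90, 50), "epi_ED")
})

test_that("agreement statistics match the closed-form OLS oracle", {
  x <- c(80, 95, 110, 120, 135, 150, 90, 105, 125, 140)
  identical_fit <- agreement_stats(x, x)
  expect_equal(identical_fit$slope, 1, tolerance = 1e-9)
  expect_equal(identical_fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(identical_fit$bias, 0, tolerance = 1e-9)

  shifted <- agreement_stats(x + 3, x)
  expect_equal(shifted$slope, 1, tolerance = 1e-9)
  expect_equal(shifted$bias, 3, tolerance = 1e-9)
  expect_equal(shifted$loa_upper, 3, tolerance = 1e-9)  # zero-SD differences

  set.seed(62)
  auto <- 1.05 * x + stats::rnorm(10, 0, 4)
  ag <- agreement_stats(auto, x)
  orc <- ols_oracle(x, auto)
  expect_equal(ag$slope, orc$slope, tolerance = 1e-9)
  expect_equal(ag$intercept, orc$intercept, tolerance = 1e-9)
  expect_equal(ag$r_squared, orc$r_squared, tolerance = 1e-9)
  expect_equal(ag$loa_upper - ag$loa_lower, 2 * 1.96 * stats::sd(auto - x),
               tolerance = 1e-9)
  expect_error(agreement_stats(auto, rep(1, 10)), "variance")

  expect_equal(nrow(tidy(ag)), 2L)
  expect_equal(glance(ag)$r_squared, orc$r_squared, tolerance = 1e-9)
  expect_s3_class(autoplot(ag), "ggplot")
  expect_s3_class(autoplot(ag, type = "bland_altman"), "ggplot")
})

test_that("pair evaluation drops missing expert contours and summarises", {
  a <- contour(circle_points(c(30, 30), 10, 60))
  b <- contour(circle_points(c(30, 30), 11, 60))
  far <- contour(circle_points(c(30, 30), 18, 60))
  pairs <- tibble::tibble(
    auto = list(a, a, a), manual = list(b, NULL, far),
    pixel_spacing_mm = 1)
  ev <- evaluate_contour_pairs(pairs)
  expect_equal(nrow(ev), 2L)               # NULL expert dropped
  expect_equal(ev$good, c(TRUE, FALSE))
  smry <- summarise_evaluation(ev)
  expect_equal(smry$percent_good, 50)
  expect_equal(smry$mean_apd_mm, ev$apd_mm[1])  # good contours only
})
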