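test_that("polar transform maps constants, disks and single pixels correctly", {
  img <- matrix(3.7, 50, 50)
  pol <- polar_transform(img, c(25, 25), 20, n_angles = 36)
  expect_true(all(abs(pol$values - 3.7) < 1e-12))

  # centered disk: every column is a step dropping at row ~ R + 1
  fx <- fixture_disk_image(64, c(32, 32), 12, 100, 0)
  pol2 <- polar_transform(fx$image, c(32, 32), 25, n_angles = 72)
  drop_row <- apply(pol2$values, 2, function(col) max(which(col > 50)))
  expect_true(all(abs(drop_row - 13) <= 1))

  # off-center bright pixel appears only at its forward-mapped (theta, r) cell
  img3 <- matrix(0, 64, 64); img3[33, 45] <- 1   # (x=44, y=32) vs pole (32,32)
  pol3 <- polar_transform(img3, c(32, 32), 20, n_angles = 90)
  nz <- which(pol3$values > 0.2, arr.ind = TRUE)
  expect_true(all(abs(nz[, 1] - 13) <= 1.5))               # r = 12 -> row 13
  expect_true(all(nz[, 2] %in% c(1, 2, 90)))               # theta ~ 0
  expect_error(polar_transform(img3, c(100, 0), 10), "outside")
})

test_that("edge features are single-row ridges after suppression", {
  # radial step edge at radius 10: one nonzero row per column, at 10/11
  m <- 30; n <- 48
  pol <- list(values = matrix(0, m, n), center = c(0, 0), radial_step = 1,
              angular_step = 2 * pi / n, r_max = m - 1)
  pol$values[1:11, ] <- 100
  class(pol) <- "lv_polar"
  f <- edge_feature(pol)
  per_col <- apply(f, 2, function(col) which(col > 0))
  expect_true(all(lengths(per_col) == 1))
  expect_true(all(unlist(per_col) %in% c(11, 12)))

  pol$values[] <- 5
  expect_true(all(edge_feature(pol) == 0))

  # pure radial ramp: constant gradient, no strict local maxima survive
  pol$values <- matrix(rep(seq_len(m), n), m, n)
  expect_true(all(edge_feature(pol) == 0))
})

test_that("search masks honour endocardium, bright regions and previous slice", {
  B <- build_search_mask(c(30, 12), rep(10, 12))
  expect_true(all(B[12:30, ]))
  expect_false(any(B[1:10, ]))

  bright <- matrix(FALSE, 30, 12); bright[20:25, 1:5] <- TRUE
  B2 <- build_search_mask(c(30, 12), rep(10, 12), bright_polar = bright)
  expect_false(any(B2 & bright))
  expect_true(all(B2[12:19, ]))

  # previous epicardial annulus at rows 12:18, radial dilation 2:
  # admissible rows within [10, 20] where not bright
  prev <- matrix(FALSE, 30, 12); prev[12:18, ] <- TRUE
  B3 <- build_search_mask(c(30, 12), rep(8, 12), bright_polar = bright,
                          previous_epi_polar = prev, dilation_rows = 2)
  rows3 <- which(B3, arr.ind = TRUE)[, 1]
  expect_true(all(rows3 >= 10 & rows3 <= 20))
  # dilation oracle: admissible set equals the explicit union of shifts
  dil <- prev
  for (k in 1:2) dil <- dil | rbind(prev[-(1:k), , drop = FALSE],
                                    matrix(FALSE, k, 12)) |
    rbind(matrix(FALSE, k, 12), prev[1:(30 - k), , drop = FALSE])
  expect_identical(unname(B3), unname(dil & !bright &
                                        outer(1:30, rep(9, 12), `>=`)))

  # fully blocked column reopens next to the endocardium
  bright_all <- matrix(TRUE, 30, 12)
  B4 <- build_search_mask(c(30, 12), rep(10, 12), bright_polar = bright_all)
  expect_true(all(colSums(B4) >= 1))
  expect_true(all(which(B4[, 1]) %in% c(11, 12)))
})

test_that("the dynamic programme follows ridges and respects tie-breaks", {
  # perfect ridge in row 2 of a 3x4 map
  f <- matrix(0, 3, 4); f[2, ] <- 1
  cm <- dp_optimal_path(f, matrix(TRUE, 3, 4), dp_params(delta = 1, gamma = 0))
  expect_equal(cm$path, rep(2L, 4))
  expect_equal(cm$cost, 0)

  # constant feature: closed constant path at the smallest admissible row
  f2 <- matrix(0.4, 6, 8)
  cm2 <- dp_optimal_path(f2, matrix(TRUE, 6, 8), dp_params(delta = 2, gamma = 0.5))
  expect_true(all(cm2$path == 1L))

  # infeasible: no admissible cell in one column
  mask <- matrix(TRUE, 5, 6); mask[, 3] <- FALSE
  expect_error(dp_optimal_path(matrix(0, 5, 6), mask), "infeasible")
})

test_that("dp agrees with exhaustive enumeration on random instances", {
  set.seed(41)
  for (i in 1:25) {
    delta <- sample(1:2, 1)
    m <- sample(5:7, 1); n <- sample(6:7, 1)
    gamma <- sample(c(0, 0.5), 1)
    inst <- random_dp_instance(m, n, delta, gamma)
    got <- dp_optimal_path(inst$feature, inst$mask, inst$params)
    orc <- dp_oracle_enum(inst$feature, inst$mask, delta, 1, gamma)
    expect_equal(got$cost, orc$cost, tolerance = 1e-12)
    expect_equal(got$path, unname(orc$path))
  }
})

test_that("dp cost is monotone in delta and gamma forces exact closure", {
  set.seed(42)
  inst <- random_dp_instance(7, 8, 1, 0.3)
  costs <- vapply(1:3, function(d) {
    dp_optimal_path(inst$feature, inst$mask,
                    dp_params(delta = d, gamma = 0.3))$cost
  }, numeric(1))
  expect_true(all(diff(costs) <= 1e-12))

  f <- matrix(stats::runif(7 * 8), 7, 8)
  cm <- dp_optimal_path(f, matrix(TRUE, 7, 8),
                        dp_params(delta = 2, gamma = 1e9))
  expect_equal(cm$path[8], cm$path[1])
})

test_that("paths map back to circles and phantom annuli", {
  img <- matrix(0, 60, 60)
  pol <- polar_transform(img, c(30, 30), 25, n_angles = 120)
  cm <- list(path = rep(16L, 120))  # constant radius 15
  ct <- epicardial_contour(cm, pol)
  r <- sqrt((ct$x - 30)^2 + (ct$y - 30)^2)
  expect_lt(max(abs(r - 15)), 1)

  # phantom annulus: recover the epicardial circle
  ph <- generate_phantom_study(phantom_spec(phases = "ED", noise_sd = 4))
  tr <- ph$truth[ph$truth$slice_index == 4, ]
  s <- ph$study$slices$ED[[5]]
  roi <- roi_spec(c(tr$center_y, tr$center_x), 40, dim(s$pixels))
  roi_img <- lvseg:::roi_crop(s$pixels, roi)
  cen <- c(tr$center_x - roi$col0, tr$center_y - roi$row0)
  pol2 <- polar_transform(roi_img, cen, 38)
  feat <- edge_feature(pol2)
  bright <- polar_transform((roi_img >= 140) * 1, cen, 38)$values > 0.5
  B <- build_search_mask(dim(feat), rep(tr$endo_radius + 1, 180), bright)
  cm2 <- dp_optimal_path(feat, B)
  ct2 <- epicardial_contour(cm2, pol2, offset = c(roi$col0, roi$row0))
  expect_gte(dice_masks(contour_mask(ct2, dim(s$pixels)), tr$epi_mask[[1]]), 0.95)

  # forward/backward consistency: polar radii of the contour match the path
  radii <- lvseg:::resample_radii(ct2, c(tr$center_x, tr$center_y), 180)
  expect_lt(max(abs(radii - (cm2$path - 1))), 1.5)
})
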