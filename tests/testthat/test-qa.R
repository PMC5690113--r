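test_that("slice profiles recover a voxelized disk radius to sub-voxel accuracy", {
  disk <- stack_to_mesh(contour_stack(list(circle_contour(20, 0, 128),
                                           circle_contour(20, 10, 128))), 0.5)
  v <- voxelize_ct(disk, spacing_mm = c(0.5, 0.5, 0.625))
  p <- extract_slice_profile(v, 5)
  r <- sqrt(rowSums(p$points^2))
  expect_true(all(abs(r - 20) <= 0.25 + 1e-9))
})

test_that("a pure-background slice yields a no-contour error", {
  v <- ct_volume(array(-1000, c(16, 16, 4)), c(1, 1, 1))
  expect_error(extract_slice_profile(v, 1, threshold_hu = -435), "no closed iso-contour")
})

test_that("raising the threshold shrinks the extracted contour (level-set monotonicity)", {
  disk <- stack_to_mesh(contour_stack(list(circle_contour(15, 0, 96),
                                           circle_contour(15, 8, 96))), 0.5)
  v <- voxelize_ct(disk, material_hu = 130, supersample = 3)
  lo <- extract_slice_profile(v, 4, threshold_hu = -435)   # midpoint
  hi <- extract_slice_profile(v, 4, threshold_hu = 100)    # near material mean
  expect_lt(abs(contour_area(hi)), abs(contour_area(lo)))
})

test_that("the conformity metric is symmetric, zero on identity, and exact on 3-4-5", {
  cn <- circle_contour(20, 0, 360)
  expect_equal(slice_conformity(cn, cn), 0)
  t <- c(0.3, 0.4)
  angle0 <- atan2(-t[2], -t[1])
  a <- circle_contour(20, 0, 360, angle0 = angle0)
  b <- contour(sweep(a$points, 2, t, `+`), 0)
  expect_equal(slice_conformity(a, b), 0.5, tolerance = 1e-12)
  expect_equal(slice_conformity(b, a), slice_conformity(a, b))
})

test_that("the conformity metric equals the all-pairs brute-force oracle", {
  for (seed in 1:25) {
    a <- random_contour(seed, n = 15 + (seed %% 4) * 20)
    b <- random_contour(seed + 100, n = 15 + ((seed + 1) %% 4) * 20)
    expect_identical(slice_conformity(a, b, max_spacing_mm = Inf),
                     hausdorff_oracle(a$points, b$points))
  }
})

test_that("self-comparison of a stack reports zero conformity error", {
  stk <- make_scalp_bolus(seed = 2)
  rep <- conformity_report(stk, stk)
  expect_equal(rep$mean_mm, 0, tolerance = 1e-9)
  expect_equal(rep$sd_mm, 0, tolerance = 1e-9)
})

test_that("a uniform 1 mm normal offset reports mean conformity 1.0 mm", {
  design <- contour_stack(lapply(seq(0, 6, 2), function(z)
    circle_contour(20, z, 360)))
  inflated <- contour_stack(lapply(seq(0, 6, 2), function(z)
    circle_contour(21, z, 360)))
  rep <- conformity_report(design, inflated)
  expect_equal(rep$mean_mm, 1.0, tolerance = 0.05)
})

test_that("disjoint z ranges are rejected", {
  a <- contour_stack(list(circle_contour(10, 0), circle_contour(10, 2)))
  b <- contour_stack(list(circle_contour(10, 10), circle_contour(10, 12)))
  expect_error(conformity_report(a, b), "overlap")
})

test_that("rigid pre-registration removes a deliberate in-plane shift", {
  stk <- make_scalp_bolus(seed = 4)
  shifted <- stk
  shifted$contours <- lapply(shifted$contours, function(c) {
    c$points <- sweep(c$points, 2, c(2.5, -1.5), `+`); c
  })
  raw <- conformity_report(stk, shifted)
  reg <- conformity_report(stk, shifted, register = TRUE)
  expect_gt(raw$mean_mm, 2)
  expect_lt(reg$mean_mm, 0.1)
  expect_true(reg$registered)
})

test_that("HU statistics on a constant volume are exact for any margin", {
  v <- ct_volume(array(130, c(20, 20, 16)), c(1, 1, 1))
  mask <- array(TRUE, dim(v$hu))
  st <- hu_stats(v, mask, 1.25)
  expect_equal(st$mean_hu, 130)
  expect_equal(st$sd_hu, 0)
})

test_that("interface erosion removes partial-volume bias from HU statistics", {
  cube <- cube_mesh(30)
  v <- voxelize_ct(cube, material_hu = -72.1, background_hu = -1000,
                   noise_sd_hu = 5.3, psf_sigma_mm = 0.4, supersample = 3,
                   seed = 13)
  mask <- v$hu > -536                               # background/material midpoint
  eroded <- hu_stats(v, mask, 1.25)
  raw <- hu_stats(v, mask, 0)
  expect_gt(eroded$n_voxels, 1e4)
  expect_lt(abs(eroded$mean_hu - (-72.1)), 0.5)
  expect_lt(abs(eroded$sd_hu - 5.3) / 5.3, 0.15)
  expect_lt(raw$mean_hu, eroded$mean_hu)            # biased toward air
  # bias shrinks monotonically with margin
  m0 <- abs(hu_stats(v, mask, 0)$mean_hu - (-72.1))
  m1 <- abs(hu_stats(v, mask, 0.75)$mean_hu - (-72.1))
  m2 <- abs(hu_stats(v, mask, 1.25)$mean_hu - (-72.1))
  expect_true(m1 < m0 && m2 < m1)
})

test_that("erosion that consumes the whole mask suggests a smaller margin", {
  v <- ct_volume(array(100, c(6, 6, 6)), c(1, 1, 1))
  mask <- array(FALSE, dim(v$hu)); mask[3:4, 3:4, 3:4] <- TRUE
  expect_error(hu_stats(v, mask, 3), "smaller margin")
})

test_that("density is mass over design volume in g/cm3", {
  expect_equal(estimate_density(1.19, cube_mesh(10)), 1.19)   # 1000 mm3 cube
  expect_equal(estimate_density(7.76, 8000), 0.97)
  expect_error(estimate_density(0, cube_mesh(10)), "positive")
})

test_that("height checks interpolate the design bilinearly and flag outliers", {
  g <- compensator_grid(matrix(25, 11, 11), c(2, 2))
  probes <- rbind(c(5, 5), c(10.7, 3.3), c(18, 18))
  hc <- height_check(g, probes, c(25, 25, 25))
  expect_true(attr(hc, "pass"))
  expect_equal(hc$deviation_mm, rep(0, 3))
  hc2 <- height_check(g, probes, c(25, 26.2, 25))
  expect_false(attr(hc2, "pass"))
  expect_equal(which(abs(hc2$deviation_mm) >= 1), 2L)
  # bilinear interpolation is exact for a linear field, probes off-node
  th <- outer(seq(0, 10, length.out = 11), seq(0, 5, length.out = 11), `+`)
  gl <- compensator_grid(th, c(2, 2))
  p <- rbind(c(3.7, 11.3), c(9.1, 0.4))
  expected <- 10 * p[, 2] / 20 + 5 * p[, 1] / 20
  hcl <- height_check(gl, p, expected)
  expect_equal(hcl$deviation_mm, c(0, 0), tolerance = 1e-12)
})

test_that("HU to relative electron density uses the user calibration with clamping", {
  tab <- data.frame(hu = c(-1000, 0), red = c(0, 1))
  expect_equal(hu_to_red(tab, 0), 1.0)
  expect_equal(hu_to_red(tab, -500), 0.5)
  expect_warning(res <- hu_to_red(tab, 500), "clamped")
  expect_equal(res, 1.0)
  expect_error(hu_to_red(data.frame(hu = 0, red = 1), 0), ">= 2 rows")
})
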