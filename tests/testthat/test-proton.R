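test_that("the analytic Bragg curve places d80 at the prescribed range", {
  b <- beam_model(15.0)
  cv <- bragg_curve(b)
  d80 <- distal_range(cv)
  expect_lt(abs(d80 - 15.0), 0.05)
  pk <- cv$depth_mm[which.max(cv$dose)] / 10
  expect_true(pk >= 15.0 - 2 * b$sigma_cm && pk <= 15.0)
  # distal falloff is monotone beyond the peak
  distal <- cv$dose[cv$depth_mm / 10 > pk]
  expect_true(all(diff(distal) <= 1e-12))
})

test_that("doubling the grid density moves d80 by less than 0.01 cm", {
  b <- beam_model(15.0)
  c1 <- bragg_curve(b, seq(0, 158, by = 0.1))
  c2 <- bragg_curve(b, seq(0, 158, by = 0.05))
  expect_lt(abs(distal_range(c1) - distal_range(c2)), 0.01)
})

test_that("a too-coarse depth grid is refused", {
  b <- beam_model(15.0)
  expect_error(bragg_curve(b, seq(0, 158, by = 1)), "too coarse")
})

test_that("shrinking straggling approaches the unconvolved power law away from the peak", {
  b1 <- beam_model(15, sigma_cm = 0.15)
  b2 <- beam_model(15, sigma_cm = 0.02)
  g <- seq(0, 156, by = 0.01)
  c2 <- bragg_curve(b2, g)
  # at mid-range, the narrow-sigma curve matches the pristine power law shape:
  # ratio of doses at two mid depths equals the analytic ratio within 1%
  r0 <- 150  # approximately R0 in mm for small sigma
  analytic_ratio <- ((r0 - 50)^(1 / b2$p - 1)) / ((r0 - 100)^(1 / b2$p - 1))
  i50 <- which.min(abs(g - 50)); i100 <- which.min(abs(g - 100))
  expect_equal(c2$dose[i50] / c2$dose[i100], analytic_ratio, tolerance = 0.01)
  expect_true(inherits(bragg_curve(b1, g), "depth_dose"))
})

test_that("slab insertion shifts the curve by its water-equivalent thickness", {
  cv <- bragg_curve(beam_model(15.0))
  expect_equal(apply_slab(cv, 3, 0)$dose, cv$dose)            # air slab
  s <- apply_slab(cv, 3, 1)                                   # water slab
  expect_equal(distal_range(cv) - distal_range(s), 3, tolerance = 1e-3)
  for (case in list(c(2, 0.9), c(3, 1.2), c(1.5, 1.05))) {
    s2 <- apply_slab(cv, case[1], case[2])
    expect_equal(distal_range(cv) - distal_range(s2), case[1] * case[2],
                 tolerance = 1e-3)
  }
  expect_error(apply_slab(cv, 20, 1), "exceeds the curve range")
})

test_that("distal range interpolates linearly and is translation-equivariant", {
  # triangle curve: peak 1.0 at depth 100 mm, linear falloff to 0 at 110 mm
  d <- seq(0, 120, by = 1)
  dose <- pmin(d / 100, pmax(0, (110 - d) / 10))
  tc <- depth_dose(d, dose)
  expect_equal(distal_range(tc, 0.8), 10.2, tolerance = 1e-12)
  expect_equal(distal_range(tc, 1.0), 10.0)
  shifted <- depth_dose(d, pmin(pmax(d - 5, 0) / 100, pmax(0, (115 - d) / 10)))
  expect_equal(distal_range(shifted, 0.8) - distal_range(tc, 0.8), 0.5,
               tolerance = 1e-12)
  flat <- depth_dose(seq(0, 10, 1), rep(1, 11))
  expect_error(distal_range(flat, 0.8), "no distal crossing")
})

test_that("the pull-back estimator recovers constructed stopping powers", {
  cv <- bragg_curve(beam_model(15.0))
  expect_equal(estimate_rsp(cv, cv, 3), 0)
  # the two printed materials of the study, as constructed truths
  expect_equal(estimate_rsp(cv, apply_slab(cv, 3, 1.10), 3), 1.10,
               tolerance = 0.005 / 1.10)
  expect_equal(estimate_rsp(cv, apply_slab(cv, 4, 0.98), 4), 0.98,
               tolerance = 0.005 / 0.98)
})

test_that("the estimate is independent of sample thickness at fixed rsp", {
  cv <- bragg_curve(beam_model(15.0))
  est <- vapply(c(1, 2, 3, 4), function(t)
    estimate_rsp(cv, apply_slab(cv, t, 1.10), t), 0)
  expect_true(all(abs(est - 1.10) < 0.005))
})

test_that("measurement noise is seeded, reproducible, and harmless at 1%", {
  cv <- bragg_curve(beam_model(15.0))
  expect_equal(add_noise(cv, 0, 1), cv)
  n1 <- add_noise(cv, 0.01, 42)
  n2 <- add_noise(cv, 0.01, 42)
  expect_identical(n1$dose, n2$dose)
  expect_false(identical(add_noise(cv, 0.01, 43)$dose, n1$dose))
  # add_noise leaves the caller RNG untouched
  set.seed(7); before <- runif(1)
  set.seed(7); invisible(add_noise(cv, 0.01, 1)); after <- runif(1)
  expect_identical(before, after)
  # small Monte Carlo recovery (the full study runs in the acceptance suite)
  s <- apply_slab(cv, 3, 1.10)
  est <- vapply(1:20, function(k)
    estimate_rsp(add_noise(cv, 0.01, k), add_noise(s, 0.01, 1000 + k), 3), 0)
  expect_lt(abs(mean(est) - 1.10) / 1.10, 0.005)
  expect_lt(stats::sd(est) / 1.10, 0.01)
})

test_that("depth-dose curves round-trip through their CSV form", {
  cv <- bragg_curve(beam_model(15.0))
  f <- withr::local_tempfile(fileext = ".csv")
  write_depth_dose(cv, f)
  back <- read_depth_dose(f)
  expect_equal(back$depth_mm, cv$depth_mm)
  expect_equal(back$dose, cv$dose, tolerance = 1e-12)
})
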