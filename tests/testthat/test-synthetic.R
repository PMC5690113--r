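test_that("the scalp bolus generator yields valid, seeded, reproducible designs", {
  s1 <- make_scalp_bolus(seed = 21)
  s2 <- make_scalp_bolus(seed = 21)
  s3 <- make_scalp_bolus(seed = 22)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
  z <- stack_z(s1)
  expect_true(all(diff(z) > 0))
  for (c in s1$contours) expect_true(is_simple_contour(c))
  expect_error(make_scalp_bolus(), "seed")
})

test_that("an unperturbed bolus matches the analytic elliptical band", {
  s <- make_scalp_bolus(outer_semiaxes_mm = c(35, 25), thickness_mm = 8,
                        perturb_amp_mm = 0)
  # central slice: outer arc radii on the 35 x 25 ellipse
  zc <- stack_z(s)[ceiling(length(s$contours) / 2)]
  # rebuild analytically for the central slice scale factor
  z_range <- range(stack_z(s))
  sfac <- 1 - 0.15 * ((zc - mean(z_range)) / (diff(z_range) / 2))^2
  cn <- s$contours[[ceiling(length(s$contours) / 2)]]
  p <- cn$points[1:60, ]                            # outer arc samples
  th <- atan2(p[, 2] / (25 * sfac), p[, 1] / (35 * sfac))
  expect_equal(p[, 1], 35 * sfac * cos(th), tolerance = 1e-9)
  expect_equal(p[, 2], 25 * sfac * sin(th), tolerance = 1e-9)
})

test_that("the compensator generator is concave, seeded, and plan-file exact", {
  g0 <- make_compensator(n_rows = 40, n_cols = 40, noise_amp_mm = 0)
  centre <- g0$thickness_mm[20, 20]
  edge <- g0$thickness_mm[1, 20]
  expect_lt(centre, edge)                           # concave bowl
  g1 <- make_compensator(n_rows = 40, n_cols = 40, seed = 5)
  expect_identical(g1, make_compensator(n_rows = 40, n_cols = 40, seed = 5))
  expect_false(identical(g1, make_compensator(n_rows = 40, n_cols = 40, seed = 6)))
  expect_true(all(g1$thickness_mm >= 0))
  f <- withr::local_tempfile(fileext = ".dcm")
  write_ion_plan(list(list(name = "b", compensator = g1)), f)
  expect_identical(read_ion_plan_compensator(f, 1)$thickness_mm, g1$thickness_mm)
})

test_that("voxelization recovers a cube volume to within one surface shell", {
  cube <- cube_mesh(30)
  v <- voxelize_ct(cube, spacing_mm = c(0.5, 0.5, 0.625))
  vol <- sum(v$hu > -435) * prod(v$spacing_mm)
  shell <- 6 * 30^2 * max(v$spacing_mm)             # one-voxel surface shell
  expect_lt(abs(vol - 27000), shell)
  expect_identical(voxelize_ct(cube, noise_sd_hu = 10, seed = 3)$hu,
                   voxelize_ct(cube, noise_sd_hu = 10, seed = 3)$hu)
})

test_that("simulated interior statistics are recovered through the QA chain", {
  cube <- cube_mesh(30)
  v <- voxelize_ct(cube, material_hu = 130.1, noise_sd_hu = 10,
                   psf_sigma_mm = 0.4, supersample = 3, seed = 17)
  st <- hu_stats(v, v$hu > -435, 1.25)
  expect_lt(abs(st$mean_hu - 130.1), 0.5)
  expect_gt(st$n_voxels, 1e4)
})

test_that("fixture DICOM workspaces round-trip through the readers", {
  d <- withr::local_tempdir()
  stk <- make_scalp_bolus(seed = 8)
  g <- make_compensator(n_rows = 30, n_cols = 30, seed = 8)
  cube <- cube_mesh(12)
  ct <- voxelize_ct(cube, noise_sd_hu = 10, seed = 8)
  ct$hu <- round(ct$hu)                             # integral HU: lossless storage
  cv <- bragg_curve(beam_model(15))
  write_fixture_dicoms(list(Bolus = stk, Beam1 = g, scan = ct, ref = cv), d)
  expect_true(file.exists(file.path(d, "manifest.json")))
  b <- read_rtstruct(file.path(d, "rtstruct.dcm"), "Bolus")
  expect_equal(stack_z(b), stack_z(stk))
  expect_equal(b$contours[[1]]$points, stk$contours[[1]]$points, tolerance = 1e-7)
  g2 <- read_ion_plan_compensator(file.path(d, "ionplan.dcm"), 1)
  expect_identical(g2$thickness_mm, g$thickness_mm)
  v2 <- read_ct_series(file.path(d, "ct_scan"))
  expect_identical(v2$hu, ct$hu)
  c2 <- read_depth_dose(file.path(d, "ref.csv"))
  expect_equal(c2$dose, cv$dose, tolerance = 1e-12)
})
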