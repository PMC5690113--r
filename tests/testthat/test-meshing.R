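test_that("a prism of identical squares reconstructs with the exact volume", {
  s <- contour_stack(lapply(seq(0, 10, 2.5), function(z) square_contour(10, z)))
  m <- stack_to_mesh(s, 1)
  v <- validate_mesh(m)
  expect_true(v$ok)
  expect_equal(mesh_volume(m), 1000, tolerance = 1e-3)
})

test_that("a cone stack matches the analytic frustum volume at 0.5 mm sampling", {
  s <- contour_stack(list(circle_contour(10, 0, n = 128),
                          circle_contour(0.5, 20, n = 128)))
  m <- stack_to_mesh(s, 0.5)
  analytic <- pi * 20 / 3 * (10^2 + 10 * 0.5 + 0.5^2)
  expect_lt(abs(mesh_volume(m) - analytic) / analytic, 0.01)
  expect_true(validate_mesh(m)$ok)
})

test_that("reconstructed surfaces are watertight with Euler characteristic 2", {
  fixtures <- list(
    stack_to_mesh(make_scalp_bolus(perturb_amp_mm = 0), 1),
    stack_to_mesh(make_scalp_bolus(seed = 3), 1.5),
    stack_to_mesh(contour_stack(list(circle_contour(8, 0), circle_contour(12, 4),
                                     circle_contour(6, 9))), 1)
  )
  for (m in fixtures) {
    v <- validate_mesh(m)
    expect_true(v$watertight)
    expect_true(v$outward)
    expect_equal(v$euler_per_component, 2)
    expect_equal(v$n_degenerate_facets, 0L)
  }
})

test_that("cap triangulations satisfy the constrained empty-circumcircle property", {
  # convex cap
  p1 <- circle_contour(15, 0, n = 80)$points
  t1 <- triangulate_polygon(p1)
  expect_true(cap_circumcircle_ok(p1, t1))
  # non-convex crescent cap (the bolus end slice)
  stk <- make_scalp_bolus(seed = 5)
  p2 <- resample_contour(stk$contours[[1]], 1.6)$points  # keep <= 200 points
  expect_lte(nrow(p2), 200L)
  t2 <- triangulate_polygon(p2)
  expect_equal(nrow(t2), nrow(p2) - 2L)             # simple polygon: n-2 triangles
  expect_true(cap_circumcircle_ok(p2, t2))
})

test_that("halving the sampling spacing changes smooth-fixture volume by < 0.5%", {
  s <- contour_stack(list(circle_contour(12, 0, 96), circle_contour(9, 6, 96),
                          circle_contour(11, 12, 96)))
  v1 <- mesh_volume(stack_to_mesh(s, 1))
  v2 <- mesh_volume(stack_to_mesh(s, 0.5))
  expect_lt(abs(v2 - v1) / v1, 0.005)
})

test_that("a constant-thickness compensator meshes to the exact box volume", {
  g <- compensator_grid(matrix(20, 11, 11), c(2, 2))
  m <- grid_to_mesh(g)
  expect_true(validate_mesh(m)$ok)
  expect_equal(mesh_volume(m), 20 * 20 * 20, tolerance = 1e-12)
})

test_that("a linear ramp meshes to mean height x footprint exactly", {
  th <- matrix(rep(seq(0, 10, length.out = 11), each = 11), 11, 11)
  g <- compensator_grid(th, c(2, 2), base_thickness_mm = 2)
  m <- grid_to_mesh(g)
  expect_equal(mesh_volume(m), mean(th + 2) * 20 * 20, tolerance = 1e-9)
})

test_that("compensator mesh volume equals the per-triangle prismatoid oracle", {
  g <- make_compensator(n_rows = 25, n_cols = 30, spacing_mm = 2, seed = 9)
  m <- grid_to_mesh(g)
  # oracle: for each grid cell, two triangles; volume = mean vertex height x
  # planar triangle area, summed (exact for linear interpolation)
  t <- g$thickness_mm + g$base_thickness_mm
  cell_area <- prod(g$pixel_spacing_mm) / 2
  vol <- 0
  for (r in 1:(nrow(t) - 1)) for (c in 1:(ncol(t) - 1)) {
    vol <- vol + cell_area * mean(c(t[r, c], t[r + 1, c], t[r + 1, c + 1])) +
                 cell_area * mean(c(t[r, c], t[r + 1, c + 1], t[r, c + 1]))
  }
  expect_equal(mesh_volume(m), vol, tolerance = 1e-9)
})

test_that("degenerate meshing inputs are rejected", {
  expect_error(stack_to_mesh(contour_stack(list(circle_contour(10, 0))), 1),
               "at least 2")
  bow <- contour(rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10)), 0)
  bad <- contour_stack(list(bow, contour(bow$points, 5, validate = FALSE)))
  expect_error(stack_to_mesh(bad, 1), "self-intersecting")
  expect_error(grid_to_mesh(compensator_grid(matrix(5, 1, 5), c(1, 1))),
               "zero area")
})

test_that("printable export scales, round-trips, and refuses open meshes", {
  g <- make_compensator(n_rows = 20, n_cols = 20, spacing_mm = 2, seed = 2)
  m <- grid_to_mesh(g)
  out <- withr::local_tempfile(fileext = ".stl")
  mesh_to_printable(m, out, scale_factors = c(0.5, 0.5, 0.5))
  back <- read_stl(out)
  expect_equal(mesh_volume(back), 0.125 * mesh_volume(m), tolerance = 1e-5)
  expect_equal(nrow(back$facets), nrow(m$facets))

  cube <- cube_mesh(10)
  open <- triangle_mesh(cube$vertices, cube$facets[-1, ])
  out2 <- withr::local_tempfile(fileext = ".stl")
  expect_error(mesh_to_printable(open, out2), "3 open edge")
  expect_false(file.exists(out2))
  expect_silent(mesh_to_printable(open, out2, force = TRUE))
  expect_true(file.exists(out2))
})
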