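test_that("ray casting finds the nearest transversal hit", {
  slab <- slab_mesh(extent = c(20, 20))
  h <- ray_first_hit(c(0, 0, -50), c(0, 0, 1), slab)
  expect_equal(h$point, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(h$distance, 50)
  expect_null(ray_first_hit(c(0, 0, -50), c(0, 0, -1), slab))
  expect_error(ray_first_hit(c(0, 0, NA), c(0, 0, 1), slab), "finite")
  expect_error(ray_first_hit(c(0, 0, 0), c(0, 0, 0), slab), "nonzero")

  # from the centre of a level-3 icosphere every direction hits within
  # the inscribed-tessellation bound
  ico <- icosphere(10, c(0, 0, 0), 3)
  set.seed(11)
  for (k in 1:25) {
    d <- stats::rnorm(3)
    h <- ray_first_hit(c(0, 0, 0), d / sqrt(sum(d^2)), ico)
    expect_true(h$distance >= 9.5 && h$distance <= 10.0)
  }
})

test_that("segment crossing counts match slab and closed-sphere geometry", {
  slab <- slab_mesh(extent = c(100, 100))
  expect_identical(segment_crossing_count(c(0, 0, -50), c(0, 0, 10), slab), 1L)
  expect_identical(segment_crossing_count(c(0, 0, -50), c(0, 0, -10), slab), 0L)
  ico <- icosphere(10, c(0, 0, 0), 2)
  # diameter contacts both surface endpoints; a longer segment crosses twice
  expect_identical(segment_crossing_count(c(-10, 0, 0), c(10, 0, 0), ico), 2L)
  expect_identical(segment_crossing_count(c(-20, 0, 0), c(20, 0, 0), ico), 2L)
  expect_identical(segment_crossing_count(c(0, 0, 0), c(20, 0, 0), ico), 1L)
  # grazing a shared grid edge counts once
  expect_identical(segment_crossing_count(c(0, 10, -5), c(0, 10, 5), slab), 1L)
})

test_that("exact segment-mesh distance agrees with analytic values", {
  risk <- icosphere(3, c(10, 0, -25), 3)
  d <- segment_mesh_distance(c(0, 0, 0), c(0, 0, -50), risk)
  expect_equal(d, 7, tolerance = 0.05 / 7)
  # through the mesh and endpoint-on-vertex cases are exactly zero
  expect_identical(segment_mesh_distance(c(0, 0, -25), c(20, 0, -25), risk), 0)
  v1 <- risk$vertices[1, ]
  expect_equal(segment_mesh_distance(v1, v1 + c(5, 0, 0), risk), 0,
               tolerance = 1e-12)
  expect_error(segment_mesh_distance(c(0, 0, 0), c(1, 0, 0),
                                     triangle_mesh(matrix(0, 0, 3),
                                                   matrix(0L, 0, 3))),
               "no faces")
})

test_that("segment-mesh distance matches the independent convex oracle", {
  set.seed(42)
  for (k in 1:40) {
    mesh <- random_soup_mesh(n_tri = 5)
    p0 <- stats::runif(3, -12, 12)
    p1 <- stats::runif(3, -12, 12)
    expect_equal(segment_mesh_distance(p0, p1, mesh),
                 oracle_segment_mesh_dist(p0, p1, mesh),
                 tolerance = 1e-6)
  }
})

test_that("segment-mesh distance is symmetric and rigid-invariant", {
  set.seed(7)
  for (k in 1:10) {
    mesh <- random_soup_mesh(n_tri = 4)
    p0 <- stats::runif(3, -12, 12); p1 <- stats::runif(3, -12, 12)
    d0 <- segment_mesh_distance(p0, p1, mesh)
    expect_equal(segment_mesh_distance(p1, p0, mesh), d0, tolerance = 1e-12)
    R <- needleplan:::random_rotation()
    tr <- stats::runif(3, -40, 40)
    m2 <- transform_mesh(mesh, R, tr)
    expect_equal(segment_mesh_distance(R %*% p0 + tr, R %*% p1 + tr, m2), d0,
                 tolerance = 1e-6)
  }
})

test_that("incremental cylinder clearance floors to the radius grid", {
  # exact clearance 6.9 mm from a plane-wall triangle
  wall <- plane_triangle_at_x(6.9)
  expect_equal(cylinder_clearance_incremental(c(0, 0, 10), c(0, 0, -10),
                                              list(wall), 10, 0.25),
               6.75)
  expect_equal(cylinder_clearance_incremental(c(0, 0, 10), c(0, 0, -10),
                                              list(), 10, 0.25), 10)
  crossing <- plane_triangle_at_x(0)
  expect_equal(cylinder_clearance_incremental(c(-5, 0, 0), c(5, 0, 0),
                                              list(crossing), 10, 0.25), 0)
  expect_error(cylinder_clearance_incremental(c(0, 0, 1), c(0, 0, -1),
                                              list(), 10, 0), "r_step")
})

test_that("incremental clearance stays within one step of the exact value", {
  set.seed(314)
  for (k in 1:30) {
    mesh <- random_soup_mesh(n_tri = 4)
    p0 <- stats::runif(3, -12, 12); p1 <- stats::runif(3, -12, 12)
    inc <- cylinder_clearance_incremental(p0, p1, list(mesh), 10, 0.25)
    exact <- min(segment_mesh_distance(p0, p1, mesh), 10)
    expect_lte(abs(inc - exact), 0.25)
    expect_lte(inc, exact + 1e-12)  # never overstates safety
  }
})

test_that("surface sampling hits the requested density and is reproducible", {
  slab <- slab_mesh(extent = c(20, 20))
  s <- sample_surface(slab, density = 9, seed = 0)
  expect_lte(abs(nrow(s$points) - 3600), 3 * sqrt(3600))
  s2 <- sample_surface(slab, density = 9, seed = 0)
  expect_identical(s$points, s2$points)
  expect_identical(s$face, s2$face)
  # samples lie on the surface with interpolated uv
  expect_true(all(abs(s$points[, 3]) < 1e-12))
  expect_equal(s$uv[, 1], (s$points[, 1] + 10) / 20, tolerance = 1e-9)
  big <- sample_surface(slab_mesh(extent = c(200, 200)), density = 0.01,
                        seed = 3)
  expect_lte(abs(nrow(big$points) - 400), 60)
  expect_error(sample_surface(slab, density = -1), "non-negative")
})

test_that("per-face sample counts follow the face areas", {
  slab <- slab_mesh(extent = c(50, 50), n = 5L)
  s <- sample_surface(slab, density = 2, seed = 123)
  counts <- tabulate(s$face, nbins = nrow(slab$faces))
  p <- face_areas(slab) / mesh_area(slab)
  expect_gt(stats::chisq.test(counts, p = p)$p.value, 0.001)
})

test_that("ray-fan sampling lands on the skin and is reproducible", {
  sc <- fixture_scene("slab_basic")
  s <- sample_rayfan(sc$targets[1, ], sc$skin, n_rays = 500, seed = 5)
  expect_gt(nrow(s$points), 0)
  expect_true(all(abs(s$points[, 3]) < 1e-9))
  s2 <- sample_rayfan(sc$targets[1, ], sc$skin, n_rays = 500, seed = 5)
  expect_identical(s$points, s2$points)
})

test_that("candidate angle measures match closed forms and flip invariance", {
  fr <- anatomical_frame()
  expect_equal(candidate_angles(c(0, 0, -1), fr),
               c(theta_axis = 0, theta_plane = 0))
  expect_equal(candidate_angles(c(0, 1, 0), fr),
               c(theta_axis = 90, theta_plane = 90))
  d <- c(0, -30, -50) / sqrt(3400)
  a <- candidate_angles(d, fr)
  expect_equal(a[["theta_axis"]], atan(30 / 50) * 180 / pi, tolerance = 1e-9)
  expect_equal(a[["theta_plane"]], asin(30 / sqrt(3400)) * 180 / pi,
               tolerance = 1e-9)
  expect_equal(candidate_angles(-d, fr), a)
  expect_error(candidate_angles(c(0, 0, 0), fr), "nonzero")
})

test_that("point-in-mesh parity classifies slab and closed shapes", {
  slab <- slab_mesh(extent = c(100, 100))
  expect_true(point_in_mesh(c(0, 0, -10), slab))
  expect_false(point_in_mesh(c(0, 0, 10), slab))
  ico <- icosphere(10, c(1, 2, 3), 2)
  expect_true(point_in_mesh(c(1, 2, 3), ico))
  expect_false(point_in_mesh(c(20, 2, 3), ico))
})
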