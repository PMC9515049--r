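p_def <- planning_params()

test_that("parameter invariants are enforced", {
  expect_error(planning_params(safety_margin = 12), "safety_margin")
  expect_error(planning_params(tilt_angle = 70), "tilt_angle")
  expect_error(planning_params(tilt_quality_breakpoint = 1), "breakpoint")
  expect_error(planning_params(max_path_length = 0), "max_path_length")
  expect_identical(p_def$clearance_backend, "exact")
})

test_that("parameter files round-trip through YAML and JSON", {
  p <- planning_params(sampling_density = 0.5, clearance_backend = "incremental")
  for (ext in c("yaml", "json")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_params(p, f)
    expect_equal(read_params(f), p)
  }
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(no_such_field = 1), f)
  expect_error(read_params(f), "unknown parameter")
})

test_that("distance score is the clamped margin-normalised clearance", {
  expect_equal(cqv_dist(10, p_def), 1)
  expect_equal(cqv_dist(2, p_def), 0)
  expect_equal(cqv_dist(6, p_def), 0.5)
  expect_equal(cqv_dist(0, p_def), 0)   # below margin clamps, not negative
  expect_equal(cqv_dist(15, p_def), 1)  # beyond max distance clamps
})

test_that("relative path-length score uses the vertical surface distance", {
  expect_equal(cqv_path(50, 50, p_def), 1)
  expect_equal(cqv_path(150, 50, p_def), 0)
  expect_equal(cqv_path(100, 50, p_def), 0.5)
  # degenerate deep target: vertical distance at/above the needle length
  expect_warning(out <- cqv_path(c(140, 160), 150, p_def), "degenerate")
  expect_equal(out, c(1, 0))
})

test_that("angle score is piecewise linear with the tilt breakpoint", {
  expect_equal(cqv_angle(25, p_def), 0.9)
  expect_equal(cqv_angle(0, p_def), 1)
  expect_equal(cqv_angle(60, p_def), 0)
  expect_equal(cqv_angle(90, p_def), 0)  # clamped beyond max angle
  expect_equal(cqv_angle(42.5, p_def), 0.45)
  # continuity at the breakpoint
  expect_lt(abs(cqv_angle(25 - 1e-9, p_def) - cqv_angle(25 + 1e-9, p_def)),
            1e-6)
})

test_that("path quality is the minimum CQV and rejects out-of-range input", {
  expect_equal(aggregate_quality(0.3, 0.8, 0.9), 0.3)
  expect_equal(aggregate_quality(1, 1, 1), 1)
  expect_equal(aggregate_quality(0.625, 1, 1), 0.625)
  expect_error(aggregate_quality(1.2, 0.5, 0.5), "\\[0, 1\\]")
  expect_error(aggregate_quality(-0.1, 0.5, 0.5), "\\[0, 1\\]")
})

test_that("CQVs are monotone in their driving quantity", {
  set.seed(99)
  cl <- sort(stats::runif(200, 0, 12))
  expect_true(all(diff(cqv_dist(cl, p_def)) >= 0))
  L <- sort(stats::runif(200, 50, 200))
  expect_true(all(diff(cqv_path(L, 50, p_def)) <= 0))
  th <- sort(stats::runif(200, 0, 90))
  expect_true(all(diff(cqv_angle(th, p_def)) <= 0))
})

test_that("hard conditions use strict boundaries and accumulate reasons", {
  hc <- function(...) check_hard_conditions(..., params = p_def)
  expect_identical(hc(1.5, 100, 30, 1L)$failure_reasons, "risk")
  expect_identical(hc(5, 160, 30, 1L)$failure_reasons, "length")
  expect_identical(hc(5, 100, 61, 1L)$failure_reasons, "angle")
  expect_identical(hc(5, 100, 30, 2L)$failure_reasons, "line_of_sight")
  # boundary values pass: clearance == margin, length == needle, angle == max
  expect_true(hc(2, 150, 60, 1L)$hard_pass)
  # all reasons are reported, not just the first
  expect_setequal(hc(1, 200, 75, 0L)$failure_reasons,
                  c("risk", "length", "angle", "line_of_sight"))
})

test_that("vertical surface distance is the up-axis depth", {
  sc <- fixture_scene("slab_basic")
  expect_equal(vertical_surface_distance(c(0, 0, -50), sc$skin, sc$frame), 50)
  expect_equal(vertical_surface_distance(c(3, 4, -1), sc$skin, sc$frame), 1)
  ell <- ellipsoid_mesh(c(150, 200, 100))
  expect_equal(vertical_surface_distance(c(0, 0, 0), ell), 100,
               tolerance = 0.005)
  expect_error(vertical_surface_distance(c(0, 0, 10), sc$skin, sc$frame),
               "no skin surface")
})

test_that("candidate evaluation reproduces the analytic slab worked examples", {
  sc_risk <- fixture_scene("slab_risk")
  cand <- evaluate_candidate(c(0, 0, 0), c(0, 0, -50), sc_risk)
  expect_true(cand$hard_pass)
  expect_equal(cand$clearance_mm, 7, tolerance = 0.01)
  expect_equal(cand$cqv_dist, 0.625, tolerance = 0.005)
  expect_equal(cand$cqv_path, 1)
  expect_equal(cand$cqv_angle, 1)
  expect_equal(cand$quality, cand$cqv_dist)

  sc <- fixture_scene("slab_basic")
  c2 <- evaluate_candidate(c(0, 30, 0), c(0, 0, -50), sc)
  expect_equal(c2$path_length_mm, sqrt(3400), tolerance = 1e-9)
  expect_equal(c2$cqv_path, 1 - (sqrt(3400) - 50) / 100, tolerance = 1e-9)
  expect_equal(c2$cqv_angle, 0.9 - 0.9 * (asin(30 / sqrt(3400)) * 180 / pi - 25) / 35,
               tolerance = 1e-9)
  expect_equal(c2$quality, c2$cqv_angle)

  # steep lateral path: hard angle failure, soft scores absent
  c3 <- evaluate_candidate(c(90, 0, 0), c(0, 0, -50), sc)
  expect_false(c3$hard_pass)
  expect_identical(c3$failure_reasons, "angle")
  expect_true(is.na(c3$quality) && is.na(c3$cqv_dist))
})

test_that("planner confines admissible paths to the max-angle cone", {
  sc <- fixture_scene("slab_basic")
  map <- plan_paths(sc, params = planning_params(sampling_density = 0.01),
                    seed = 2)
  cand <- map$candidates
  r_lat <- sqrt(cand$x^2 + cand$y^2)
  r_cone <- 50 * tan(60 * pi / 180)
  spacing <- 1 / sqrt(0.01)
  expect_true(all(r_lat[cand$hard_pass] <= r_cone + spacing))
  expect_true(all(!cand$hard_pass[r_lat > r_cone + 1e-9]))
  expect_identical(map$counts[["sampled"]], nrow(cand))
  expect_identical(map$counts[["hard_pass"]], sum(cand$hard_pass))
  # determinism
  map2 <- plan_paths(sc, params = planning_params(sampling_density = 0.01),
                     seed = 2)
  expect_identical(map$candidates, map2$candidates)
})

test_that("a risk structure blocking the vertical corridor fails candidates", {
  sc <- make_slab_scene(
    slab_extent = c(120, 120), target_depth = 50,
    risks = list(list(shape = "sphere", radius = 6, center = c(0, 0, -25))))
  map <- plan_paths(sc, params = planning_params(sampling_density = 0.02),
                    seed = 4)
  cand <- map$candidates
  near_axis <- sqrt(cand$x^2 + cand$y^2) < 5
  expect_true(any(near_axis))
  expect_true(all(grepl("risk", cand$failure_reasons[near_axis])))
  # moving the risk closer to a fixed path never increases quality
  path_q <- function(offset) {
    s <- make_slab_scene(slab_extent = c(120, 120), target_depth = 50,
                         risks = list(list(shape = "sphere", radius = 3,
                                           center = c(offset, 0, -25))))
    evaluate_candidate(c(0, 0, 0), c(0, 0, -50), s)$quality
  }
  qs <- vapply(c(14, 11, 8, 6), path_q, numeric(1))
  expect_true(all(diff(qs) <= 1e-12))
})

test_that("exact and incremental backends agree within one radius step", {
  sc <- fixture_scene("slab_risk")
  pe <- planning_params(sampling_density = 0.005)
  pi_ <- planning_params(sampling_density = 0.005,
                         clearance_backend = "incremental")
  me <- plan_paths(sc, params = pe, seed = 9)
  mi <- plan_paths(sc, params = pi_, seed = 9)
  expect_identical(nrow(me$candidates), nrow(mi$candidates))
  both <- me$candidates$hard_pass & mi$candidates$hard_pass
  dq <- abs(me$candidates$cqv_dist[both] - mi$candidates$cqv_dist[both])
  expect_true(all(dq <= 0.25 / (10 - 2) + 1e-12))
})

test_that("zero sampling density yields an empty map with zero counts", {
  sc <- fixture_scene("slab_basic")
  map <- plan_paths(sc, params = planning_params(sampling_density = 0),
                    seed = 1)
  expect_identical(nrow(map$candidates), 0L)
  expect_true(all(map$counts == 0))
})

test_that("candidate tables round-trip through CSV", {
  sc <- fixture_scene("slab_risk")
  map <- plan_paths(sc, params = planning_params(sampling_density = 0.005),
                    seed = 6)
  f <- tempfile(fileext = ".csv")
  write_candidates(map, f)
  back <- read_candidates(f)
  expect_identical(nrow(back), nrow(map$candidates))
  expect_identical(back$hard_pass, map$candidates$hard_pass)
  expect_identical(back$failure_reasons, map$candidates$failure_reasons)
  expect_equal(back$quality, map$candidates$quality, tolerance = 1e-9)
})
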