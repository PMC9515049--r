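#' Soft condition quality values (CQVs)
#'
#' The three condition quality values rate an admissible path on a `[0, 1]`
#' scale, 1 being optimal; all are clamped into `[0, 1]`.
#'
#' `cqv_dist()` rewards clearance from risk structures:
#' `(clearance - margin) / (max_eval_distance - margin)`. A path exactly at
#' the safety margin scores 0; clearance at or beyond the maximum evaluated
#' distance scores 1.
#'
#' `cqv_path()` rates path length relative to the target's vertical surface
#' distance, so deep targets are not penalised for being deep:
#' `1 - (L - L_vert) / (L_max - L_vert)`. The shortest possible (vertical)
#' path scores 1; a path as long as the needle scores 0. In the degenerate
#' case `L_vert >= L_max` the score is 1 if `L <= L_vert` and 0 otherwise.
#'
#' `cqv_angle()` rates the angle to the transverse imaging plane, because
#' in-plane paths are easiest to track and CT gantries can tilt up to about
#' `tilt_angle`: angles up to the tilt map linearly onto
#' `[breakpoint, 1]`, larger angles up to `max_angle` map linearly onto
#' `[0, breakpoint]`, and angles beyond `max_angle` clamp to 0. The two
#' branches agree at the tilt angle, where the score equals the breakpoint.
#'
#' @param clearance path clearance in mm (capped upstream at
#'   `max_eval_distance`).
#' @param path_length insertion-point-to-target distance in mm.
#' @param vert_dist vertical surface distance of the target in mm.
#' @param theta_plane angle between path and transverse plane, degrees.
#' @param params a [planning_params()].
#' @return a numeric score in `[0, 1]` (vectorised over the first argument).
#' @export
#' @examples
#' p <- planning_params()
#' cqv_dist(6, p)        # 0.5
#' cqv_path(100, 50, p)  # 0.5
#' cqv_angle(25, p)      # 0.9, the breakpoint
cqv_dist <- function(clearance, params = planning_params()) {
  stopifnot(all(clearance >= 0))
  clamp01((clearance - params$safety_margin) /
          (params$max_eval_distance - params$safety_margin))
}

#' @rdname cqv_dist
#' @export
cqv_path <- function(path_length, vert_dist, params = planning_params()) {
  stopifnot(all(path_length > 0), all(vert_dist > 0))
  lmax <- params$max_path_length
  if (any(vert_dist >= lmax)) {
    warning("vertical surface distance >= max path length; ",
            "degenerate relative length score", call. = FALSE)
  }
  degenerate <- (path_length * 0 + vert_dist) >= lmax  # recycled to length
  out <- ifelse(degenerate,
                as.numeric(path_length <= vert_dist),
                1 - (path_length - vert_dist) / (lmax - vert_dist))
  clamp01(out)
}

#' @rdname cqv_dist
#' @export
cqv_angle <- function(theta_plane, params = planning_params()) {
  stopifnot(all(theta_plane >= 0), all(theta_plane <= 90))
  b <- params$tilt_quality_breakpoint
  tilt <- params$tilt_angle
  amax <- params$max_angle
  out <- ifelse(theta_plane <= tilt,
                1 - theta_plane * (1 - b) / tilt,
                b - b * (theta_plane - tilt) / (amax - tilt))
  clamp01(out)
}

#' Path quality value: minimum of the three CQVs
#'
#' The per-path rating is the minimum of the three condition quality
#' values rather than a weighted combination, so a path can only score
#' high when it has no weak condition; trading a risk against another
#' condition's benefit is left to the user.
#'
#' @param cqv_dist,cqv_path,cqv_angle scores in `[0, 1]`.
#' @return the path quality value, in `[0, 1]`.
#' @export
#' @examples
#' aggregate_quality(0.625, 1, 1)  # 0.625
aggregate_quality <- function(cqv_dist, cqv_path, cqv_angle) {
  v <- c(cqv_dist, cqv_path, cqv_angle)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1)) {
    stop("CQVs must lie in [0, 1]", call. = FALSE)
  }
  pmin(cqv_dist, pmin(cqv_path, cqv_angle))
}

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Vertical surface distance of a target
#'
#' Depth of the target below the skin along the frame's up axis, measured
#' by a ray cast from the target vertically upwards to the skin surface.
#' It is the target-specific reference for the relative path-length score.
#'
#' @param target length-3 point inside the skin (mm).
#' @param skin skin [triangle_mesh()].
#' @param frame an [anatomical_frame()].
#' @return distance in mm.
#' @export
vertical_surface_distance <- function(target, skin, frame = anatomical_frame()) {
  hit <- ray_first_hit(target, frame$up_axis, skin)
  if (is.null(hit)) {
    stop(sprintf("no skin surface vertically above target (%g, %g, %g)",
                 target[1], target[2], target[3]), call. = FALSE)
  }
  hit$distance
}

#' Hard admissibility conditions
#'
#' Screens a candidate path against the four hard conditions. All violated
#' conditions are reported, not only the first:
#' * `risk` — clearance below the safety margin (a path exactly at the
#'   margin passes, with a distance score of 0);
#' * `length` — path strictly longer than the needle;
#' * `angle` — angle to the vertical axis strictly above `max_angle`;
#' * `line_of_sight` — the target-to-insertion segment does not cross the
#'   skin exactly once (at the insertion point).
#'
#' @param clearance mm.
#' @param path_length mm.
#' @param theta_axis degrees.
#' @param skin_crossings integer crossing count of the path with the skin.
#' @param params a [planning_params()].
#' @return list with `hard_pass` (logical) and `failure_reasons`
#'   (character vector, empty when passing).
#' @export
check_hard_conditions <- function(clearance, path_length, theta_axis,
                                  skin_crossings, params = planning_params()) {
  reasons <- character(0)
  if (clearance < params$safety_margin) reasons <- c(reasons, "risk")
  if (path_length > params$max_path_length) reasons <- c(reasons, "length")
  if (theta_axis > params$max_angle) reasons <- c(reasons, "angle")
  if (skin_crossings != 1L) reasons <- c(reasons, "line_of_sight")
  list(hard_pass = length(reasons) == 0L, failure_reasons = reasons)
}

#' Evaluate one candidate access path
#'
#' Computes the full geometry of the path from a skin sample to the
#' target, screens the hard conditions, and — only for admissible paths —
#' the three soft condition quality values and their minimum, the path
#' quality value. Hard-failed candidates carry `NA` scores (unsuitable,
#' not worst-suitable). Clearance is evaluated with the configured backend
#' and capped at `max_eval_distance` before scoring.
#'
#' @param insertion_point length-3 point on the skin (mm).
#' @param target length-3 point inside the skin (mm).
#' @param scene a [scene()].
#' @param params a [planning_params()].
#' @param vert_dist optional precomputed vertical surface distance of the
#'   target (mm); computed when `NULL`.
#' @param uv optional length-2 texture coordinate of the insertion point.
#' @return a one-row data frame (a `candidate_path` record) with columns
#'   x, y, z, u, v, path_length_mm, clearance_mm, theta_axis_deg,
#'   theta_plane_deg, vertical_surface_distance_mm, skin_crossings,
#'   hard_pass, failure_reasons, cqv_dist, cqv_path, cqv_angle, quality.
#' @export
evaluate_candidate <- function(insertion_point, target, scene,
                               params = planning_params(),
                               vert_dist = NULL, uv = NULL) {
  insertion_point <- as_point3(insertion_point, "insertion_point")
  target <- as_point3(target, "target")
  d <- target - insertion_point
  path_length <- sqrt(sum(d^2))
  if (path_length < 1e-9) stop("insertion point equals target", call. = FALSE)
  ang <- candidate_angles(d / path_length, scene$frame)
  if (is.null(vert_dist)) {
    vert_dist <- vertical_surface_distance(target, scene$skin, scene$frame)
  }
  clearance <- switch(params$clearance_backend,
    exact = clearance_exact(target, insertion_point, scene$risks,
                            r_max = params$max_eval_distance),
    incremental = cylinder_clearance_incremental(
      target, insertion_point, scene$risks,
      r_max = params$max_eval_distance, r_step = params$clearance_r_step))
  crossings <- segment_crossing_count(target, insertion_point, scene$skin)
  hard <- check_hard_conditions(clearance, path_length, ang[["theta_axis"]],
                                crossings, params)
  if (hard$hard_pass) {
    cd <- cqv_dist(clearance, params)
    cp <- cqv_path(path_length, vert_dist, params)
    ca <- cqv_angle(ang[["theta_plane"]], params)
    q <- aggregate_quality(cd, cp, ca)
  } else {
    cd <- cp <- ca <- q <- NA_real_
  }
  data.frame(
    x = insertion_point[1], y = insertion_point[2], z = insertion_point[3],
    u = if (is.null(uv)) NA_real_ else uv[1],
    v = if (is.null(uv)) NA_real_ else uv[2],
    path_length_mm = path_length,
    clearance_mm = clearance,
    theta_axis_deg = ang[["theta_axis"]],
    theta_plane_deg = ang[["theta_plane"]],
    vertical_surface_distance_mm = vert_dist,
    skin_crossings = as.integer(crossings),
    hard_pass = hard$hard_pass,
    failure_reasons = paste(hard$failure_reasons, collapse = ";"),
    cqv_dist = cd, cqv_path = cp, cqv_angle = ca, quality = q
  )
}

#' Plan access paths for one target
#'
#' End-to-end planning pipeline: samples candidate insertion points on the
#' skin (area-uniform by default, or a target-centred ray fan), evaluates
#' each candidate's hard conditions and — for admissible paths — soft
#' scores, and returns the full insertion map with provenance.
#' Deterministic for a fixed seed.
#'
#' @param scene a [scene()].
#' @param target_index which target of the scene to plan for.
#' @param params a [planning_params()].
#' @param seed integer seed for the surface sampler.
#' @param sampler `"surface"` (area-uniform at `params$sampling_density`)
#'   or `"rayfan"` (target-centred scanner-style rays; ray count chosen so
#'   the expected number of skin hits matches the surface sampler).
#' @return an `insertion_map`: list with `candidates` (data frame, one row
#'   per sample), `scene`, `params`, `target_index`, `seed`, `sampler` and
#'   `counts` (sampled, hard_pass, and per-failure-reason tallies).
#' @export
#' @examples
#' sc <- make_slab_scene(slab_extent = c(60, 60), target_depth = 30)
#' m <- plan_paths(sc, params = planning_params(sampling_density = 0.02),
#'                 seed = 1)
#' m$counts
plan_paths <- function(scene, target_index = 1L, params = planning_params(),
                       seed = 0L, sampler = c("surface", "rayfan")) {
  sampler <- match.arg(sampler)
  validate_scene(scene)
  target <- scene$targets[target_index, ]
  if (sampler == "surface") {
    s <- sample_surface(scene$skin, params$sampling_density, seed = seed)
  } else {
    n_rays <- max(1L, as.integer(round(
      params$sampling_density * mesh_area(scene$skin))))
    s <- sample_rayfan(target, scene$skin, n_rays, seed = seed)
  }
  n <- nrow(s$points)
  vert_dist <- vertical_surface_distance(target, scene$skin, scene$frame)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- evaluate_candidate(
      s$points[i, ], target, scene, params,
      vert_dist = vert_dist,
      uv = if (is.null(s$uv)) NULL else s$uv[i, ])
  }
  candidates <- if (n > 0L) do.call(rbind, rows) else empty_candidates()
  new_insertion_map(candidates, scene, params, target_index, seed, sampler)
}

empty_candidates <- function() {
  evaluate_candidate(c(0, 0, 0), c(0, 0, -1),
                     list(skin = slab_mesh(extent = c(2, 2)),
                          risks = list(), frame = anatomical_frame()),
                     planning_params())[0, ]
}

new_insertion_map <- function(candidates, scene, params, target_index,
                              seed, sampler) {
  reasons <- c("risk", "length", "angle", "line_of_sight")
  fr <- strsplit(candidates$failure_reasons, ";", fixed = TRUE)
  tally <- vapply(reasons, function(r) {
    sum(vapply(fr, function(x) r %in% x, logical(1)))
  }, integer(1))
  structure(list(
    candidates = candidates,
    scene = scene,
    params = params,
    target_index = as.integer(target_index),
    seed = seed,
    sampler = sampler,
    counts = c(sampled = nrow(candidates),
               hard_pass = sum(candidates$hard_pass),
               tally)
  ), class = "insertion_map")
}

#' @export
print.insertion_map <- function(x, ...) {
  cat(sprintf("<insertion_map: %d candidates, %d admissible (target %d, seed %s, %s sampler)>\n",
              x$counts[["sampled"]], x$counts[["hard_pass"]],
              x$target_index, format(x$seed), x$sampler))
  if (x$counts[["hard_pass"]] > 0) {
    q <- x$candidates$quality[x$candidates$hard_pass]
    cat(sprintf("  path quality: min %.3f  median %.3f  max %.3f\n",
                min(q), stats::median(q), max(q)))
  }
  invisible(x)
}

#' @export
as.data.frame.insertion_map <- function(x, ...) x$candidates

#' Export / import the candidate table as CSV
#'
#' One row per evaluated candidate with geometry, hard-condition verdicts
#' and scores. `read_candidates()` restores the data frame with the same
#' column types.
#'
#' @param map an `insertion_map` (or its candidate data frame).
#' @param path CSV file path.
#' @return `write_candidates()`: the path, invisibly; `read_candidates()`:
#'   the candidate data frame.
#' @export
write_candidates <- function(map, path) {
  df <- if (inherits(map, "insertion_map")) map$candidates else map
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_candidates
#' @export
read_candidates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$failure_reasons[is.na(df$failure_reasons)] <- ""
  df$hard_pass <- as.logical(df$hard_pass)
  df
}
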