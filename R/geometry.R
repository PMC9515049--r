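#' First ray-mesh intersection
#'
#' Casts a ray from `origin` along `direction` and returns the nearest
#' transversal intersection with the mesh, if any.
#'
#' @param origin length-3 ray origin (mm).
#' @param direction length-3 direction; need not be unit length.
#' @param mesh a [triangle_mesh()].
#' @return `NULL` if the ray misses, else a list with `point` (hit
#'   coordinates), `distance` (mm from origin) and `face` (1-based index).
#' @export
#' @examples
#' slab <- slab_mesh(extent = c(20, 20))
#' ray_first_hit(c(0, 0, -50), c(0, 0, 1), slab)$distance  # 50
ray_first_hit <- function(origin, direction, mesh) {
  origin <- as_point3(origin, "origin")
  direction <- as_point3(direction, "direction")
  dn <- sqrt(sum(direction^2))
  if (dn < 1e-12) stop("direction must be nonzero", call. = FALSE)
  direction <- direction / dn
  hits <- .cpp_line_hits(origin, direction, mesh$vertices, mesh$faces)
  if (nrow(hits) == 0L) return(NULL)
  keep <- hits[, 1] > 1e-9
  if (!any(keep)) return(NULL)
  hits <- hits[keep, , drop = FALSE]
  i <- which.min(hits[, 1])
  t <- hits[i, 1]
  list(point = origin + t * direction, distance = t,
       face = as.integer(hits[i, 2]))
}

#' Number of transversal segment-mesh crossings
#'
#' Counts how often the segment from `p0` to `p1` crosses the mesh surface,
#' endpoints included. Intersections closer together than `tol` millimetres
#' (e.g. a crossing exactly on an edge shared by two faces) are counted once.
#'
#' The planner uses this for the line-of-sight hard condition: a valid
#' access path crosses the skin exactly once, at the insertion point.
#'
#' @param p0,p1 segment endpoints (mm).
#' @param mesh a [triangle_mesh()].
#' @param tol deduplication tolerance in mm.
#' @return integer crossing count.
#' @export
segment_crossing_count <- function(p0, p1, mesh, tol = 1e-9) {
  p0 <- as_point3(p0, "p0"); p1 <- as_point3(p1, "p1")
  d <- p1 - p0
  len <- sqrt(sum(d^2))
  if (len < 1e-12) stop("p0 and p1 must differ", call. = FALSE)
  hits <- .cpp_line_hits(p0, d, mesh$vertices, mesh$faces)
  if (nrow(hits) == 0L) return(0L)
  ttol <- max(tol / len, 1e-12)
  t <- sort(hits[hits[, 1] >= -ttol & hits[, 1] <= 1 + ttol, 1])
  if (length(t) == 0L) return(0L)
  # cluster t-values within tolerance: shared-edge hits collapse to one
  sum(c(TRUE, diff(t) > ttol))
}

#' Exact minimum segment-to-mesh distance
#'
#' Exact minimum Euclidean distance between the segment `[p0, p1]` and any
#' triangle of the mesh; zero when they intersect. This is the exact form
#' of the planner's clearance ("distance to risk structures") and the
#' reference the incremental cylinder method is checked against.
#'
#' @inheritParams segment_crossing_count
#' @return distance in mm.
#' @export
segment_mesh_distance <- function(p0, p1, mesh) {
  p0 <- as_point3(p0, "p0"); p1 <- as_point3(p1, "p1")
  if (sqrt(sum((p1 - p0)^2)) < 1e-12) stop("p0 and p1 must differ", call. = FALSE)
  if (nrow(mesh$faces) == 0L) stop("mesh has no faces", call. = FALSE)
  .cpp_segment_mesh_distance(p0, p1, mesh$vertices, mesh$faces)
}

#' Incremental-cylinder clearance
#'
#' Clearance of a path by radius growth: a cylinder is laid around the
#' segment from target to insertion point and its radius grown in steps of
#' `r_step` up to `r_max`. As soon as a radius overlaps a risk structure
#' the growth stops and the last non-overlapping radius is the clearance,
#' so the method never overstates safety. With no overlap at all the
#' clearance is `r_max`.
#'
#' @param p0,p1 segment endpoints (mm).
#' @param risks list of [triangle_mesh()] risk structures.
#' @param r_max maximum evaluated radius (mm).
#' @param r_step radius increment (mm).
#' @return clearance in mm, a multiple of `r_step` or `r_max`.
#' @export
cylinder_clearance_incremental <- function(p0, p1, risks, r_max = 10,
                                           r_step = 0.25) {
  if (r_step <= 0) stop("r_step must be positive", call. = FALSE)
  if (r_max < r_step) stop("r_max must be at least r_step", call. = FALSE)
  if (length(risks) == 0L) return(r_max)
  # a cylinder of radius r about the segment overlaps a mesh iff the
  # segment-to-mesh distance is below r
  dmin <- min(vapply(risks, function(m) segment_mesh_distance(p0, p1, m),
                     numeric(1)))
  radii <- seq(0, r_max, by = r_step)
  if (radii[length(radii)] < r_max) radii <- c(radii, r_max)
  ok <- radii[dmin >= radii]  # largest tested radius with no overlap
  if (length(ok) == 0L) 0 else max(ok)
}

#' Exact capped clearance of a path
#'
#' Minimum segment-to-risk distance capped at `r_max`; the default
#' clearance backend.
#'
#' @inheritParams cylinder_clearance_incremental
#' @return clearance in mm, in `[0, r_max]`.
#' @export
clearance_exact <- function(p0, p1, risks, r_max = 10) {
  if (length(risks) == 0L) return(r_max)
  dmin <- min(vapply(risks, function(m) segment_mesh_distance(p0, p1, m),
                     numeric(1)))
  min(dmin, r_max)
}

#' Area-weighted random surface sampling
#'
#' Samples points uniformly on a mesh surface at a prescribed density.
#' The number of samples is Poisson with mean `density * mesh_area(mesh)`,
#' faces are chosen with probability proportional to their area, and
#' points are uniform within each face. Texture coordinates are
#' barycentrically interpolated when the mesh carries them. Reproducible
#' for a fixed `seed`.
#'
#' @param mesh a [triangle_mesh()] with positive area.
#' @param density target density in points per mm^2.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return list with `points` (n x 3), `face` (n), and `uv` (n x 2 or NULL).
#' @export
#' @examples
#' s <- sample_surface(slab_mesh(extent = c(20, 20)), density = 1, seed = 1)
#' nrow(s$points) / 400  # close to 1 point per mm^2
sample_surface <- function(mesh, density, seed = NULL) {
  if (!is.numeric(density) || density < 0) {
    stop("density must be non-negative", call. = FALSE)
  }
  areas <- face_areas(mesh)
  total <- sum(areas)
  if (total <= 0) stop("mesh has zero surface area", call. = FALSE)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  n <- stats::rpois(1, density * total)
  if (n == 0L) {
    return(list(points = matrix(numeric(0), 0, 3), face = integer(0),
                uv = if (is.null(mesh$uv)) NULL else matrix(numeric(0), 0, 2)))
  }
  fi <- sample.int(nrow(mesh$faces), n, replace = TRUE, prob = areas)
  r1 <- sqrt(stats::runif(n))
  r2 <- stats::runif(n)
  w1 <- 1 - r1
  w2 <- r1 * (1 - r2)
  w3 <- r1 * r2
  V <- mesh$vertices
  F <- mesh$faces[fi, , drop = FALSE]
  pts <- w1 * V[F[, 1], , drop = FALSE] +
         w2 * V[F[, 2], , drop = FALSE] +
         w3 * V[F[, 3], , drop = FALSE]
  uv <- NULL
  if (!is.null(mesh$uv)) {
    U <- mesh$uv
    uv <- w1 * U[F[, 1], , drop = FALSE] +
          w2 * U[F[, 2], , drop = FALSE] +
          w3 * U[F[, 3], , drop = FALSE]
  }
  list(points = pts, face = fi, uv = uv)
}

#' Target-centred ray-fan surface sampling
#'
#' Alternative sampler mirroring a scanner that casts rays outward from the
#' target: `n_rays` quasi-uniform sphere directions (Fibonacci lattice,
#' randomly rotated per seed) are cast from the target and the first skin
#' hit of each becomes a candidate insertion point. Surface density then
#' varies with distance and incidence angle, unlike [sample_surface()].
#'
#' @param target length-3 point inside the skin (mm).
#' @param mesh skin [triangle_mesh()].
#' @param n_rays number of rays.
#' @param seed integer seed for the random lattice rotation.
#' @return list with `points`, `face`, `uv` as in [sample_surface()].
#' @export
sample_rayfan <- function(target, mesh, n_rays, seed = NULL) {
  target <- as_point3(target, "target")
  if (n_rays < 1) stop("n_rays must be at least 1", call. = FALSE)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  i <- seq_len(n_rays) - 0.5
  phi <- pi * (3 - sqrt(5)) * i
  z <- 1 - 2 * i / n_rays
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  dirs <- dirs %*% t(random_rotation())
  pts <- matrix(NA_real_, n_rays, 3)
  fcs <- integer(n_rays)
  for (k in seq_len(n_rays)) {
    h <- ray_first_hit(target, dirs[k, ], mesh)
    if (!is.null(h)) {
      pts[k, ] <- h$point
      fcs[k] <- h$face
    }
  }
  keep <- !is.na(pts[, 1])
  pts <- pts[keep, , drop = FALSE]
  fcs <- fcs[keep]
  uv <- NULL
  if (!is.null(mesh$uv) && nrow(pts) > 0L) {
    uv <- interpolate_uv(mesh, pts, fcs)
  }
  list(points = pts, face = fcs, uv = uv)
}

# Barycentric uv interpolation of points known to lie on given faces.
interpolate_uv <- function(mesh, points, faces) {
  V <- mesh$vertices
  U <- mesh$uv
  F <- mesh$faces[faces, , drop = FALSE]
  out <- matrix(NA_real_, nrow(points), 2)
  for (k in seq_len(nrow(points))) {
    a <- V[F[k, 1], ]; b <- V[F[k, 2], ]; cc <- V[F[k, 3], ]
    v0 <- b - a; v1 <- cc - a; v2 <- points[k, ] - a
    d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
    d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
    den <- d00 * d11 - d01 * d01
    v <- (d11 * d20 - d01 * d21) / den
    w <- (d00 * d21 - d01 * d20) / den
    out[k, ] <- (1 - v - w) * U[F[k, 1], ] + v * U[F[k, 2], ] + w * U[F[k, 3], ]
  }
  out
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Insertion-angle measures of a path direction
#'
#' Two angle measures of a candidate path: `theta_axis`, the angle between
#' the path and the vertical (sagittal) axis, used by the hard angle
#' condition; and `theta_plane`, the angle between the path and the
#' transverse imaging plane, used by the soft angle condition. Both are in
#' degrees in `[0, 90]` and invariant to flipping the direction.
#'
#' @param direction length-3 path direction.
#' @param frame an [anatomical_frame()].
#' @return named numeric vector `c(theta_axis=, theta_plane=)` in degrees.
#' @export
#' @examples
#' candidate_angles(c(0, 0, -1), anatomical_frame())  # 0, 0
candidate_angles <- function(direction, frame) {
  d <- as_point3(direction, "direction")
  n <- sqrt(sum(d^2))
  if (n < 1e-12) stop("direction must be nonzero", call. = FALSE)
  d <- d / n
  ca <- min(1, abs(sum(d * frame$up_axis)))
  sp <- min(1, abs(sum(d * frame$longitudinal_axis)))
  c(theta_axis = acos(ca) * 180 / pi,
    theta_plane = asin(sp) * 180 / pi)
}

#' Point-in-mesh test by crossing parity
#'
#' Parity of the number of surface crossings of a ray from the point along
#' (approximately) the frame's up axis: odd means inside. The slight
#' perturbation of the ray direction avoids grazing hits on vertices of
#' symmetric meshes. For open meshes such as a slab skin this tests "below
#' the surface" along the up axis.
#'
#' @param point length-3 query point (mm).
#' @param mesh a [triangle_mesh()].
#' @param frame an [anatomical_frame()] supplying the ray direction.
#' @return logical.
#' @export
point_in_mesh <- function(point, mesh, frame = anatomical_frame()) {
  point <- as_point3(point, "point")
  third <- cross3(frame$up_axis, frame$longitudinal_axis)
  dir <- frame$up_axis + 1.7e-4 * frame$longitudinal_axis + 3.1e-4 * third
  far <- point + dir / sqrt(sum(dir^2)) * 1e6
  (segment_crossing_count(point, far, mesh) %% 2L) == 1L
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
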