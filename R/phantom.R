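#' Rectangular slab skin mesh
#'
#' Planar "skin" patch at z = 0 with outward normal +z, centred on the
#' origin, triangulated on a regular grid and carrying planar texture
#' coordinates. Slab scenes make every planning quantity available in
#' closed form (vertical surface distance equals target depth, clearances
#' and angles are analytic), which is what the test oracles rely on.
#'
#' @param extent length-2 extent in mm (x, y).
#' @param n grid subdivisions per side.
#' @param label mesh label.
#' @return a [triangle_mesh()] with uv coordinates.
#' @export
slab_mesh <- function(extent = c(200, 200), n = 10L, label = "skin") {
  w <- extent[1]; h <- extent[2]
  xs <- seq(-w / 2, w / 2, length.out = n + 1L)
  ys <- seq(-h / 2, h / 2, length.out = n + 1L)
  g <- expand.grid(x = xs, y = ys)
  verts <- cbind(g$x, g$y, 0)
  uv <- cbind((g$x + w / 2) / w, (g$y + h / 2) / h)
  idx <- function(i, j) (j - 1L) * (n + 1L) + i
  faces <- matrix(0L, 2L * n * n, 3L)
  k <- 1L
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      a <- idx(i, j); b <- idx(i + 1L, j)
      c2 <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
      faces[k, ] <- c(a, b, c2); k <- k + 1L
      faces[k, ] <- c(a, c2, d); k <- k + 1L
    }
  }
  triangle_mesh(verts, faces, uv = uv, label = label)
}

#' Icosphere mesh
#'
#' Subdivided icosahedron projected onto a sphere; closed, watertight and
#' outward-oriented. At subdivision level 3 the sagitta (maximum radial
#' shortfall of a face centre) is below 0.005 r, i.e. under 0.05 mm for a
#' 10 mm sphere, which sets the analytic-versus-mesh tolerance used in the
#' tests.
#'
#' @param radius sphere radius in mm.
#' @param center length-3 centre (mm).
#' @param subdivisions subdivision level (0 = icosahedron).
#' @param label mesh label.
#' @return a [triangle_mesh()].
#' @export
icosphere <- function(radius = 1, center = c(0, 0, 0), subdivisions = 3L,
                      label = "") {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    res <- subdivide_tri(v, f)
    v <- res$v / sqrt(rowSums(res$v^2))
    f <- res$f
  }
  verts <- v * radius
  verts <- verts + matrix(center, nrow(verts), 3, byrow = TRUE)
  m <- triangle_mesh(verts, f, label = label)
  orient_outward(m)
}

# One loop-style 4:1 subdivision with midpoint vertex sharing.
subdivide_tri <- function(v, f) {
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  cache <- new.env(parent = emptyenv())
  verts <- v
  midpoint <- function(a, b) {
    k <- edge_key(a, b)
    if (!is.null(cache[[k]])) return(cache[[k]])
    verts <<- rbind(verts, (v[a, ] + v[b, ]) / 2)
    cache[[k]] <- nrow(verts)
    nrow(verts)
  }
  nf <- matrix(0L, 4L * nrow(f), 3L)
  for (i in seq_len(nrow(f))) {
    a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
    ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
    nf[4L * i - 3L, ] <- c(a, ab, ca)
    nf[4L * i - 2L, ] <- c(b, bc, ab)
    nf[4L * i - 1L, ] <- c(cc, ca, bc)
    nf[4L * i, ] <- c(ab, bc, ca)
  }
  list(v = verts, f = nf)
}

orient_outward <- function(mesh) {
  if (mesh_volume(mesh) < 0) {
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  }
  mesh
}

#' Ellipsoid mesh with cylindrical texture unwrap
#'
#' Icosphere scaled anisotropically to the given semi-axes, with texture
#' coordinates from a cylindrical unwrap about the longitudinal (+y) axis.
#'
#' @param semi_axes length-3 semi-axes (mm) along x, y, z.
#' @param center length-3 centre (mm).
#' @param subdivisions icosphere subdivision level.
#' @param label mesh label.
#' @return a [triangle_mesh()] with uv coordinates.
#' @export
ellipsoid_mesh <- function(semi_axes = c(150, 200, 100), center = c(0, 0, 0),
                           subdivisions = 3L, label = "skin") {
  m <- icosphere(1, c(0, 0, 0), subdivisions, label = label)
  unit <- m$vertices
  m$vertices <- sweep(unit, 2, semi_axes, `*`)
  m$vertices <- m$vertices + matrix(center, nrow(unit), 3, byrow = TRUE)
  u <- atan2(unit[, 1], -unit[, 3]) / (2 * pi) + 0.5
  v <- (unit[, 2] + 1) / 2
  m$uv <- cbind(u, v)
  orient_outward(m)
}

#' Capped tube (cylinder) mesh
#'
#' Closed cylinder between two axis points, used as a vessel-like risk
#' structure.
#'
#' @param start,end axis endpoints (mm).
#' @param radius tube radius (mm).
#' @param n_seg circumferential segments.
#' @param label mesh label.
#' @return a [triangle_mesh()].
#' @export
tube_mesh <- function(start, end, radius, n_seg = 24L, label = "") {
  start <- as_point3(start, "start"); end <- as_point3(end, "end")
  axis <- end - start
  len <- sqrt(sum(axis^2))
  if (len < 1e-9) stop("tube must have positive length", call. = FALSE)
  w <- axis / len
  a <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- cross3(w, a); u <- u / sqrt(sum(u^2))
  v <- cross3(w, u)
  ang <- 2 * pi * (seq_len(n_seg) - 1L) / n_seg
  ring <- t(vapply(ang, function(t) radius * (cos(t) * u + sin(t) * v),
                   numeric(3)))
  bottom <- ring + matrix(start, n_seg, 3, byrow = TRUE)
  top <- ring + matrix(end, n_seg, 3, byrow = TRUE)
  verts <- rbind(bottom, top, start, end)
  cb <- 2L * n_seg + 1L  # bottom cap centre
  ct <- 2L * n_seg + 2L  # top cap centre
  faces <- matrix(0L, 4L * n_seg, 3L)
  for (i in seq_len(n_seg)) {
    j <- if (i == n_seg) 1L else i + 1L
    faces[4L * i - 3L, ] <- c(i, j, n_seg + i)
    faces[4L * i - 2L, ] <- c(j, n_seg + j, n_seg + i)
    faces[4L * i - 1L, ] <- c(cb, j, i)
    faces[4L * i, ] <- c(ct, n_seg + i, n_seg + j)
  }
  m <- triangle_mesh(verts, faces, label = label)
  orient_outward(m)
}

make_risk_mesh <- function(spec, subdivisions = 3L) {
  shape <- match.arg(spec$shape, c("sphere", "tube"))
  label <- if (is.null(spec$label)) shape else spec$label
  if (shape == "sphere") {
    icosphere(spec$radius, spec$center, subdivisions, label = label)
  } else {
    tube_mesh(spec$start, spec$end, spec$radius, label = label)
  }
}

#' Analytic slab scene
#'
#' A planar skin patch at z = 0 with targets vertically below the origin
#' and optional risk structures. Every planning quantity has a closed
#' form: the vertical surface distance equals the target depth, the
#' clearance of the vertical path from a lateral sphere at offset `o` with
#' radius `r` is `o - r`, and the admissible region of the angle hard
#' condition is the disc of radius `depth * tan(max_angle)`.
#'
#' @param slab_extent length-2 extent (mm).
#' @param target_depth numeric vector of target depths below the surface
#'   (mm); targets sit at `(0, 0, -depth)`.
#' @param risks list of risk specs, each a list with `shape` (`"sphere"`
#'   or `"tube"`), `radius`, and `center` (sphere) or `start`/`end`
#'   (tube), plus optional `label`.
#' @param n grid subdivisions of the slab.
#' @param subdivisions icosphere level for sphere risks.
#' @return a [scene()].
#' @export
#' @examples
#' sc <- make_slab_scene(target_depth = 50,
#'                       risks = list(list(shape = "sphere", radius = 3,
#'                                         center = c(10, 0, -25))))
#' vertical_surface_distance(sc$targets[1, ], sc$skin)  # 50
make_slab_scene <- function(slab_extent = c(200, 200), target_depth = 50,
                            risks = list(), n = 10L, subdivisions = 3L) {
  skin <- slab_mesh(extent = slab_extent, n = n)
  risk_meshes <- lapply(risks, make_risk_mesh, subdivisions = subdivisions)
  targets <- cbind(0, 0, -target_depth)
  scene(skin, risk_meshes, targets, anatomical_frame())
}

#' Torso-like ellipsoid phantom
#'
#' A closed ellipsoid "torso" skin (default semi-axes 150 x 200 x 100 mm,
#' roughly desk-scale torso proportions) with embedded risk structures: a
#' longitudinal tube emulating a major vessel and a sphere emulating an
#' organ at risk. Deterministic for a fixed spec; texture coordinates come
#' from a cylindrical unwrap about the longitudinal axis.
#'
#' @param semi_axes length-3 skin semi-axes (mm).
#' @param targets n x 3 matrix or length-3 vector of target points (mm).
#' @param risks list of risk specs as in [make_slab_scene()]; `NULL` uses
#'   the default vessel tube and organ sphere.
#' @param subdivisions icosphere subdivision level for skin and spheres.
#' @param seed recorded for provenance; generation itself is
#'   deterministic.
#' @return a [scene()].
#' @export
make_torso_phantom <- function(semi_axes = c(150, 200, 100),
                               targets = c(0, 0, 0),
                               risks = NULL, subdivisions = 3L, seed = 0L) {
  if (is.null(risks)) {
    risks <- list(
      list(shape = "tube", start = c(40, -80, -30), end = c(40, 80, -30),
           radius = 8, label = "vessel"),
      list(shape = "sphere", center = c(-50, 30, -20), radius = 20,
           label = "organ"))
  }
  skin <- ellipsoid_mesh(semi_axes, subdivisions = subdivisions)
  risk_meshes <- lapply(risks, make_risk_mesh, subdivisions = subdivisions)
  if (is.null(dim(targets))) targets <- matrix(targets, ncol = 3, byrow = TRUE)
  sc <- scene(skin, risk_meshes, targets, anatomical_frame())
  # generation invariants: risks strictly inside the skin, targets clear
  # of every risk by more than the default safety margin
  for (m in sc$risks) {
    inside <- apply(m$vertices, 1, point_in_mesh, mesh = skin,
                    frame = sc$frame)
    if (!all(inside)) {
      stop(sprintf("risk '%s' is not strictly inside the skin", m$label),
           call. = FALSE)
    }
  }
  margin <- planning_params()$safety_margin
  for (i in seq_len(nrow(sc$targets))) {
    for (m in sc$risks) {
      d <- min(sqrt(colSums((t(m$vertices) - sc$targets[i, ])^2)))
      if (point_in_mesh(sc$targets[i, ], m, sc$frame) || d <= margin) {
        stop(sprintf("target %d violates risk '%s'", i, m$label),
             call. = FALSE)
      }
    }
  }
  attr(sc, "seed") <- seed
  sc
}

#' Named fixture scenes
#'
#' Small registered scenes used across the tests and documentation:
#' `"slab_basic"` (200 x 200 mm slab, one target 50 mm deep, no risks),
#' `"slab_risk"` (the same plus a 3 mm risk sphere at lateral offset
#' 10 mm, half way down the vertical path) and `"torso_basic"` (the
#' default torso phantom).
#'
#' @param name fixture name.
#' @return a [scene()].
#' @export
fixture_scene <- function(name = c("slab_basic", "slab_risk", "torso_basic")) {
  name <- match.arg(name)
  switch(name,
    slab_basic = make_slab_scene(slab_extent = c(200, 200), target_depth = 50),
    slab_risk = make_slab_scene(
      slab_extent = c(200, 200), target_depth = 50,
      risks = list(list(shape = "sphere", radius = 3, center = c(10, 0, -25),
                        label = "vessel"))),
    torso_basic = make_torso_phantom())
}
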