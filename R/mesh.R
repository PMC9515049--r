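#' Triangle mesh in millimetres
#'
#' Lightweight triangle-mesh container used throughout the planner: a
#' vertex matrix, a face index matrix and optional per-vertex texture
#' coordinates. Degenerate (zero-area) faces and unreferenced vertices are
#' removed at construction so downstream predicates can assume a clean mesh.
#'
#' @param vertices numeric matrix, one row per vertex, columns x, y, z (mm).
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param uv optional numeric matrix of per-vertex texture coordinates in
#'   `[0, 1]^2`, one row per vertex.
#' @param label short text label (e.g. `"skin"`, `"vessel"`).
#'
#' @return An object of class `triangle_mesh` with elements `vertices`,
#'   `faces`, `uv` (or `NULL`) and `label`.
#' @export
#' @examples
#' m <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                    rbind(c(1, 2, 3)), label = "tri")
#' mesh_area(m)
triangle_mesh <- function(vertices, faces, uv = NULL, label = "") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns", call. = FALSE)
  if (!all(is.finite(vertices))) stop("vertices must be finite", call. = FALSE)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(faces) != 3L) stop("faces must have 3 columns", call. = FALSE)
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face indices out of range", call. = FALSE)
  }
  if (!is.null(uv)) {
    uv <- as.matrix(uv)
    storage.mode(uv) <- "double"
    dimnames(uv) <- NULL
    if (nrow(uv) != nrow(vertices) || ncol(uv) != 2L) {
      stop("uv must be an n_vertices x 2 matrix", call. = FALSE)
    }
  }
  m <- structure(list(vertices = vertices, faces = faces, uv = uv,
                      label = as.character(label)[1]),
                 class = "triangle_mesh")
  clean_mesh(m)
}

# Drop zero-area faces; keep vertex table intact (indices stay valid).
clean_mesh <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(mesh)
  a <- face_areas(mesh)
  keep <- a > 1e-12
  if (!all(keep)) mesh$faces <- mesh$faces[keep, , drop = FALSE]
  mesh
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh '%s': %d vertices, %d faces%s>\n",
              x$label, nrow(x$vertices), nrow(x$faces),
              if (is.null(x$uv)) "" else ", uv"))
  invisible(x)
}

#' Per-face and total surface area
#'
#' @param mesh a [triangle_mesh()].
#' @return `face_areas()`: numeric vector of triangle areas (mm^2);
#'   `mesh_area()`: their sum.
#' @export
face_areas <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  if (nrow(F) == 0L) return(numeric(0))
  a <- V[F[, 1], , drop = FALSE]
  e1 <- V[F[, 2], , drop = FALSE] - a
  e2 <- V[F[, 3], , drop = FALSE] - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' @rdname face_areas
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

#' Signed volume of a closed mesh
#'
#' Sum of signed tetrahedron volumes against the origin; positive for a
#' closed, outward-oriented surface.
#'
#' @param mesh a [triangle_mesh()].
#' @return signed volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  if (nrow(F) == 0L) return(0)
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  cx <- b[, 2] * c[, 3] - b[, 3] * c[, 2]
  cy <- b[, 3] * c[, 1] - b[, 1] * c[, 3]
  cz <- b[, 1] * c[, 2] - b[, 2] * c[, 1]
  sum(a[, 1] * cx + a[, 2] * cy + a[, 3] * cz) / 6
}

#' Rigidly transform a mesh
#'
#' @param mesh a [triangle_mesh()].
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 offset (mm).
#' @return the transformed mesh.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  mesh$vertices <- mesh$vertices %*% t(rotation) +
    matrix(translation, nrow(mesh$vertices), 3, byrow = TRUE)
  mesh
}

#' Anatomical reference frame
#'
#' Encodes the patient axes the planner's angle measures refer to: the
#' vertical (sagittal) up axis and the longitudinal (cranio-caudal) axis.
#' The transverse imaging plane is the plane normal to the longitudinal
#' axis. Defaults describe a supine patient: +z anterior, +y cranial.
#'
#' @param up_axis unit vector of the vertical axis.
#' @param longitudinal_axis unit vector of the cranio-caudal axis.
#' @return an `anatomical_frame` object.
#' @export
#' @examples
#' anatomical_frame()  # +z up, +y cranial
anatomical_frame <- function(up_axis = c(0, 0, 1),
                             longitudinal_axis = c(0, 1, 0)) {
  up <- as.numeric(up_axis)
  lo <- as.numeric(longitudinal_axis)
  if (length(up) != 3L || length(lo) != 3L || !all(is.finite(c(up, lo)))) {
    stop("frame axes must be finite length-3 vectors", call. = FALSE)
  }
  nu <- sqrt(sum(up^2)); nl <- sqrt(sum(lo^2))
  if (nu < 1e-12 || nl < 1e-12) stop("frame axes must be nonzero", call. = FALSE)
  up <- up / nu; lo <- lo / nl
  if (abs(sum(up * lo)) > 1e-9) {
    stop("frame axes must be orthogonal", call. = FALSE)
  }
  structure(list(up_axis = up, longitudinal_axis = lo),
            class = "anatomical_frame")
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat(sprintf("<anatomical_frame up=(%g,%g,%g) long=(%g,%g,%g)>\n",
              x$up_axis[1], x$up_axis[2], x$up_axis[3],
              x$longitudinal_axis[1], x$longitudinal_axis[2],
              x$longitudinal_axis[3]))
  invisible(x)
}

as_point3 <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) != 3L || !all(is.finite(p))) {
    stop(sprintf("%s must be a finite length-3 vector", what), call. = FALSE)
  }
  p
}
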