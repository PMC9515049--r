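#' Quality-class colour scheme
#'
#' Insertion points are divided into four quality classes over the path
#' quality value and encoded on a single-hue green scale where darker
#' shades mean better paths. Inadmissible (hard-failed) candidates are
#' hidden, never shown as "worst".
#'
#' Three display modes exist: `"full"` colours each admissible point by
#' its class; `"area"` shows the admissible region in one uniform colour
#' with no quality coding; `"baseline"` shows nothing.
#'
#' @param boundaries strictly increasing breakpoints over `[0, 1]`
#'   (defaults to equal-width quartile bins); the top bin is right-closed.
#' @param colors character vector of hex colours, worst to best class;
#'   length must be `length(boundaries) - 1`.
#' @param mode `"full"`, `"area"` or `"baseline"`.
#' @param area_color colour used for every admissible point in area mode.
#' @return a `quality_class_scheme` object.
#' @export
#' @examples
#' s <- quality_class_scheme()
#' classify_quality(c(0.1, 0.6, 1.0), s)  # 0, 2, 3
quality_class_scheme <- function(boundaries = c(0, 0.25, 0.5, 0.75, 1),
                                 colors = c("#edf8e9", "#bae4b3",
                                            "#74c476", "#238b45"),
                                 mode = c("full", "area", "baseline"),
                                 area_color = "#74c476") {
  mode <- match.arg(mode)
  boundaries <- as.numeric(boundaries)
  if (any(diff(boundaries) <= 0)) {
    stop("class boundaries must be strictly increasing", call. = FALSE)
  }
  if (abs(boundaries[1]) > 1e-12 ||
      abs(boundaries[length(boundaries)] - 1) > 1e-12) {
    stop("class boundaries must cover [0, 1]", call. = FALSE)
  }
  if (length(colors) != length(boundaries) - 1L) {
    stop("need one colour per class", call. = FALSE)
  }
  structure(list(boundaries = boundaries, colors = colors, mode = mode,
                 area_color = area_color),
            class = "quality_class_scheme")
}

#' Classify path quality values
#'
#' Bins path quality values into the scheme's classes. With the default
#' scheme the bins are `[0, 0.25)`, `[0.25, 0.5)`, `[0.5, 0.75)` and
#' `[0.75, 1]`; class indices run from 0 (worst) to 3 (best). `NA`
#' qualities (hard-failed, unsuitable paths) map to `NA`.
#'
#' @param quality numeric vector in `[0, 1]`, `NA` for unsuitable paths.
#' @param scheme a [quality_class_scheme()].
#' @return integer vector of 0-based class indices, `NA` for unsuitable.
#' @export
classify_quality <- function(quality, scheme = quality_class_scheme()) {
  ok <- !is.na(quality)
  if (any(quality[ok] < 0 | quality[ok] > 1)) {
    stop("quality must lie in [0, 1]", call. = FALSE)
  }
  cls <- rep(NA_integer_, length(quality))
  cls[ok] <- findInterval(quality[ok], scheme$boundaries,
                          rightmost.closed = TRUE) - 1L
  cls
}

#' Display colour of a quality class
#'
#' Resolves a class index to its display colour under the scheme's mode:
#' the class colour in full mode, the single uniform colour in area mode,
#' and `NA` (transparent) in baseline mode or for unsuitable candidates.
#'
#' @param class_index integer vector of 0-based class indices (`NA` =
#'   unsuitable).
#' @param scheme a [quality_class_scheme()].
#' @param mode override of the scheme's mode.
#' @return character vector of hex colours, `NA` for hidden points.
#' @export
class_color <- function(class_index, scheme = quality_class_scheme(),
                        mode = scheme$mode) {
  mode <- match.arg(mode, c("full", "area", "baseline"))
  out <- rep(NA_character_, length(class_index))
  shown <- !is.na(class_index)
  if (mode == "baseline") return(out)
  if (any(class_index[shown] < 0 |
          class_index[shown] >= length(scheme$colors))) {
    stop("class index out of range", call. = FALSE)
  }
  out[shown] <- if (mode == "area") scheme$area_color else
    scheme$colors[class_index[shown] + 1L]
  out
}

#' Rasterise an insertion map into a texture image
#'
#' Builds the skin texture of the insertion-point visualization: each
#' admissible candidate splats its class colour (or the uniform area
#' colour) at its texture coordinate; every other texel is black. Texels
#' between samples take the colour of their nearest candidate within one
#' sampling spacing, so the admissible region reads as a continuous
#' surface; texels whose nearest candidate is hard-failed stay black
#' (unsuitable paths are hidden, and the lit area is an unbiased estimate
#' of the admissible skin area).
#'
#' @param map an `insertion_map` whose candidates carry texture
#'   coordinates.
#' @param scheme a [quality_class_scheme()].
#' @param resolution image side length in texels.
#' @return a `resolution x resolution x 3` array in `[0, 1]`, v axis up.
#' @export
render_heatmap <- function(map, scheme = quality_class_scheme(),
                           resolution = 256L) {
  img <- array(0, c(resolution, resolution, 3L))
  cand <- map$candidates
  if (nrow(cand) == 0L || scheme$mode == "baseline") return(img)
  if (all(is.na(cand$u))) {
    stop("candidates carry no texture coordinates; ",
         "generate the scene skin with a uv unwrap", call. = FALSE)
  }
  shown <- !is.na(cand$u)
  if (!any(cand$hard_pass & shown)) return(img)
  cls <- classify_quality(cand$quality[shown], scheme)
  cols <- class_color(cls, scheme)           # NA for hard-failed: hidden
  rgb <- matrix(0, length(cols), 3)
  ok <- !is.na(cols)
  rgb[ok, ] <- t(grDevices::col2rgb(cols[ok])) / 255
  # fill radius: one sampling spacing, converted from mm to texels via
  # the mesh's 3D-area-to-uv-area ratio
  spacing_mm <- 1 / sqrt(max(map$params$sampling_density, 1e-12))
  mm_per_uv <- sqrt(mesh_area(map$scene$skin) / uv_area(map$scene$skin))
  r_px <- max(1L, as.integer(ceiling(spacing_mm / mm_per_uv * resolution)))
  px <- pmin(resolution, pmax(1L, as.integer(ceiling(cand$u[shown] * resolution))))
  py <- pmin(resolution, pmax(1L, as.integer(ceiling(cand$v[shown] * resolution))))
  # nearest-candidate fill on the splat neighbourhood
  off <- expand.grid(dx = -r_px:r_px, dy = -r_px:r_px)
  off <- off[off$dx^2 + off$dy^2 <= r_px^2, ]
  owner_dist <- matrix(Inf, resolution, resolution)
  for (k in seq_len(nrow(off))) {
    qx <- px + off$dx[k]
    qy <- py + off$dy[k]
    inb <- qx >= 1L & qx <= resolution & qy >= 1L & qy <= resolution
    if (!any(inb)) next
    d2 <- off$dx[k]^2 + off$dy[k]^2
    ij <- cbind(qx[inb], qy[inb])
    better <- d2 < owner_dist[ij]
    if (!any(better)) next
    ijb <- ij[better, , drop = FALSE]
    owner_dist[ijb] <- d2
    sel <- which(inb)[better]
    img[cbind(ijb[, 1], ijb[, 2], 1L)] <- rgb[sel, 1]
    img[cbind(ijb[, 1], ijb[, 2], 2L)] <- rgb[sel, 2]
    img[cbind(ijb[, 1], ijb[, 2], 3L)] <- rgb[sel, 3]
  }
  img
}

uv_area <- function(mesh) {
  if (is.null(mesh$uv)) stop("mesh has no texture coordinates", call. = FALSE)
  U <- mesh$uv
  F <- mesh$faces
  a <- U[F[, 1], , drop = FALSE]
  e1 <- U[F[, 2], , drop = FALSE] - a
  e2 <- U[F[, 3], , drop = FALSE] - a
  sum(abs(e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])) / 2
}

#' Write a heatmap texture as PNG
#'
#' @param img array from [render_heatmap()].
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
write_heatmap_png <- function(img, path) {
  # image array is (u, v, channel) with v up; PNG wants row-major top-down
  png::writePNG(aperm(img[, dim(img)[2]:1, , drop = FALSE], c(2, 1, 3)), path)
  invisible(path)
}

#' Vertex-coloured skin mesh of an insertion map
#'
#' Colours every skin vertex by the class colour of its nearest candidate
#' when that candidate lies within one sampling spacing and is admissible;
#' vertices nearest to a hard-failed (hidden) candidate, and vertices with
#' no candidate in range, are black. In baseline mode the whole mesh is
#' black.
#'
#' @param map an `insertion_map`.
#' @param scheme a [quality_class_scheme()].
#' @param path optional output path; when given, the coloured mesh is
#'   written as PLY with per-vertex RGB.
#' @return the skin mesh with a `"color"` attribute (n x 3 integer 0-255).
#' @export
export_colored_mesh <- function(map, scheme = quality_class_scheme(),
                                path = NULL) {
  skin <- map$scene$skin
  nv <- nrow(skin$vertices)
  col <- matrix(0L, nv, 3L)
  cand <- map$candidates
  if (scheme$mode != "baseline" && any(cand$hard_pass)) {
    pts <- as.matrix(cand[, c("x", "y", "z")])
    nn <- .cpp_nearest_point(skin$vertices, pts)
    spacing_mm <- 1 / sqrt(max(map$params$sampling_density, 1e-12))
    cls <- classify_quality(cand$quality, scheme)
    owner <- cls[nn$index]
    hit <- nn$distance <= spacing_mm & !is.na(owner)
    if (any(hit)) {
      cols <- class_color(owner[hit], scheme)
      col[hit, ] <- t(grDevices::col2rgb(cols))
    }
  }
  attr(skin, "color") <- col
  if (!is.null(path)) write_ply(skin, path, color = col)
  skin
}

#' Target-depth overlay geometry
#'
#' Computes the geometry shared by the three target-visualization
#' concepts. The target is projected vertically up onto the skin; the
#' depth below the skin drives each concept's depth encoding:
#' * 3D-Object: a 20 mm wireframe sphere at the target with a reference
#'   line of alternating 10 mm x 2.5 mm cylinders from skin to target,
#'   one cylinder per started centimetre of depth;
#' * Ring: a 15-segment ring at the projection point filled clockwise
#'   like a loading bar, one segment per centimetre of depth;
#' * Position Pin: a pin at the projection point showing the depth in
#'   centimetres with exactly one decimal place.
#'
#' @param target length-3 target point (mm), inside the skin.
#' @param sc a [scene()].
#' @return a `target_overlay` list with `projection_point`, `depth_mm`,
#'   `pin_text`, `ring_segment_count` (15), `ring_fill_fraction`,
#'   `reference_cylinder_count`, `cylinder_height_mm` (10),
#'   `cylinder_diameter_mm` (2.5) and `sphere_diameter_mm` (20).
#' @export
#' @examples
#' sc <- fixture_scene("slab_basic")
#' ov <- compute_target_overlay(sc$targets[1, ], sc)
#' ov$pin_text            # "5.0"
#' ov$ring_fill_fraction  # 5/15
compute_target_overlay <- function(target, sc) {
  target <- as_point3(target, "target")
  hit <- ray_first_hit(target, sc$frame$up_axis, sc$skin)
  if (is.null(hit)) {
    stop("no skin surface vertically above the target", call. = FALSE)
  }
  depth_cm <- hit$distance / 10
  structure(list(
    projection_point = hit$point,
    depth_mm = hit$distance,
    pin_text = sprintf("%.1f", depth_cm),
    ring_segment_count = 15L,
    ring_fill_fraction = min(depth_cm / 15, 1),
    reference_cylinder_count = as.integer(ceiling(depth_cm)),
    cylinder_height_mm = 10,
    cylinder_diameter_mm = 2.5,
    sphere_diameter_mm = 20
  ), class = "target_overlay")
}

#' @export
print.target_overlay <- function(x, ...) {
  cat(sprintf("<target_overlay: depth %.1f mm, pin \"%s\", ring fill %.3f, %d cylinder(s)>\n",
              x$depth_mm, x$pin_text, x$ring_fill_fraction,
              x$reference_cylinder_count))
  invisible(x)
}

#' Write target-overlay metadata as JSON
#'
#' @param overlay a `target_overlay`.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_overlay_json <- function(overlay, path) {
  jsonlite::write_json(unclass(overlay), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
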