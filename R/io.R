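#' Read a surface mesh from STL, OBJ or PLY
#'
#' Format is chosen by file extension. STL may be binary or ASCII (the
#' solid/facet text form is detected); OBJ supports `v`, `vt` and
#' triangular `f` records including `v/vt/vn` references; PLY is read in
#' the ASCII form with optional per-vertex texture coordinates (`s`/`t`,
#' `u`/`v` or `texture_u`/`texture_v`) and `uchar` RGB colours.
#'
#' @param path mesh file.
#' @param label label for the resulting mesh (defaults to the file stem).
#' @return a [triangle_mesh()]; colours, when present in a PLY, are
#'   attached as attribute `"color"` (n x 3 integer, 0-255).
#' @export
read_mesh <- function(path, label = NULL) {
  if (!file.exists(path)) stop("mesh file not found: ", path, call. = FALSE)
  if (is.null(label)) label <- tools::file_path_sans_ext(basename(path))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl(path, label),
         obj = read_obj(path, label),
         ply = read_ply(path, label),
         stop("unsupported mesh format: .", ext, call. = FALSE))
}

read_stl <- function(path, label) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", 80)
  close(con)
  is_ascii <- identical(tolower(rawToChar(head[1:5])), "solid") &&
    any(grepl("facet", readLines(path, n = 20, warn = FALSE), fixed = TRUE))
  if (is_ascii) read_stl_ascii(path, label) else read_stl_binary(path, label)
}

read_stl_ascii <- function(path, label) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex", lines, value = TRUE)
  coords <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), function(x) {
    as.numeric(x[2:4])
  }))
  stl_soup_to_mesh(coords, label)
}

read_stl_binary <- function(path, label) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  coords <- matrix(NA_real_, 3 * n, 3)
  for (i in seq_len(n)) {
    rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
    coords[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    readBin(con, "raw", 2)
  }
  stl_soup_to_mesh(coords, label)
}

# STL stores a triangle soup; merge coincident vertices.
stl_soup_to_mesh <- function(coords, label) {
  key <- apply(round(coords, 9), 1, paste, collapse = ",")
  idx <- match(key, unique(key))
  verts <- coords[!duplicated(key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  triangle_mesh(verts, faces, label = label)
}

read_obj <- function(path, label) {
  lines <- readLines(path, warn = FALSE)
  tok <- strsplit(trimws(lines), "\\s+")
  tag <- vapply(tok, function(x) if (length(x)) x[1] else "", character(1))
  verts <- do.call(rbind, lapply(tok[tag == "v"], function(x) as.numeric(x[2:4])))
  vts <- tok[tag == "vt"]
  uv_table <- if (length(vts)) {
    do.call(rbind, lapply(vts, function(x) as.numeric(x[2:3])))
  } else NULL
  frecs <- tok[tag == "f"]
  if (length(frecs) == 0L) stop("OBJ has no faces", call. = FALSE)
  faces <- matrix(NA_integer_, length(frecs), 3)
  vtidx <- matrix(NA_integer_, length(frecs), 3)
  for (i in seq_along(frecs)) {
    parts <- strsplit(frecs[[i]][2:4], "/", fixed = TRUE)
    faces[i, ] <- vapply(parts, function(p) as.integer(p[1]), integer(1))
    vtidx[i, ] <- vapply(parts, function(p) {
      if (length(p) >= 2 && nzchar(p[2])) as.integer(p[2]) else NA_integer_
    }, integer(1))
  }
  uv <- NULL
  if (!is.null(uv_table) && !anyNA(vtidx)) {
    # per-vertex uv: take the uv of the first corner referencing each vertex
    uv <- matrix(NA_real_, nrow(verts), 2)
    uv[as.vector(faces), ] <- uv_table[as.vector(vtidx), , drop = FALSE]
    if (anyNA(uv)) uv <- NULL
  }
  triangle_mesh(verts, faces, uv = uv, label = label)
}

read_ply <- function(path, label) {
  lines <- readLines(path, warn = FALSE)
  if (!identical(trimws(lines[1]), "ply")) stop("not a PLY file", call. = FALSE)
  hend <- match("end_header", trimws(lines))
  if (is.na(hend)) stop("PLY header not terminated", call. = FALSE)
  header <- trimws(lines[seq_len(hend)])
  if (!any(grepl("^format ascii", header))) {
    stop("only ASCII PLY is supported", call. = FALSE)
  }
  nv <- as.integer(sub("^element vertex\\s+", "",
                       grep("^element vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub("^element face\\s+", "",
                       grep("^element face", header, value = TRUE)[1]))
  # vertex property names, in order of appearance between the two elements
  vstart <- grep("^element vertex", header)[1]
  fstart <- grep("^element face", header)[1]
  props <- sub("^property\\s+\\S+\\s+", "",
               grep("^property", header[(vstart + 1):(fstart - 1)], value = TRUE))
  body <- lines[(hend + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  vdat <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                                as.numeric))
  colnames(vdat) <- props[seq_len(ncol(vdat))]
  verts <- vdat[, c("x", "y", "z"), drop = FALSE]
  uv <- NULL
  for (pair in list(c("s", "t"), c("u", "v"), c("texture_u", "texture_v"))) {
    if (all(pair %in% props)) {
      uv <- vdat[, pair, drop = FALSE]
      colnames(uv) <- NULL
      break
    }
  }
  color <- NULL
  if (all(c("red", "green", "blue") %in% props)) {
    color <- vdat[, c("red", "green", "blue"), drop = FALSE]
    storage.mode(color) <- "integer"
    dimnames(color) <- NULL
  }
  fdat <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- do.call(rbind, lapply(fdat, function(x) {
    n <- as.integer(x[1])
    if (n != 3L) stop("only triangular PLY faces are supported", call. = FALSE)
    as.integer(x[2:4]) + 1L
  }))
  m <- triangle_mesh(verts, faces, uv = uv, label = label)
  if (!is.null(color)) attr(m, "color") <- color
  m
}

#' Write a mesh as ASCII PLY
#'
#' Writes vertices, faces and — when present — per-vertex texture
#' coordinates (`s`, `t`) and per-vertex RGB colours (`uchar`).
#'
#' @param mesh a [triangle_mesh()].
#' @param path output file.
#' @param color optional n x 3 integer matrix of 0-255 RGB values (or the
#'   `"color"` attribute of the mesh when `NULL`).
#' @return the path, invisibly.
#' @export
write_ply <- function(mesh, path, color = NULL) {
  if (is.null(color)) color <- attr(mesh, "color")
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  has_uv <- !is.null(mesh$uv)
  has_col <- !is.null(color)
  if (has_col) {
    color <- as.matrix(color)
    stopifnot(nrow(color) == nv, ncol(color) == 3)
    storage.mode(color) <- "integer"
  }
  header <- c(
    "ply", "format ascii 1.0",
    sprintf("comment label %s", mesh$label),
    sprintf("element vertex %d", nv),
    "property float x", "property float y", "property float z",
    if (has_uv) c("property float s", "property float t"),
    if (has_col) c("property uchar red", "property uchar green",
                   "property uchar blue"),
    sprintf("element face %d", nf),
    "property list uchar int vertex_indices",
    "end_header")
  vparts <- list(format(mesh$vertices[, 1], trim = TRUE, digits = 10),
                 format(mesh$vertices[, 2], trim = TRUE, digits = 10),
                 format(mesh$vertices[, 3], trim = TRUE, digits = 10))
  if (has_uv) {
    vparts <- c(vparts, list(format(mesh$uv[, 1], trim = TRUE, digits = 10),
                             format(mesh$uv[, 2], trim = TRUE, digits = 10)))
  }
  if (has_col) {
    vparts <- c(vparts, list(color[, 1], color[, 2], color[, 3]))
  }
  vlines <- do.call(paste, vparts)
  flines <- paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                  mesh$faces[, 3] - 1L)
  writeLines(c(header, vlines, flines), path)
  invisible(path)
}
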