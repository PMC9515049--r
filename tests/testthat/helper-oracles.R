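# Independent pure-R geometry oracles, deliberately implemented with a
# different algorithm than the package kernels: point-to-triangle distance
# by plane projection + barycentric test + edge clamping, and
# segment-to-mesh distance by 1-D convex minimisation along the segment
# (the distance from a moving point on a line to a convex triangle is
# convex in the line parameter).

oracle_point_segment_dist <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab * ab)
  t <- min(1, max(0, t))
  sqrt(sum((p - (a + t * ab))^2))
}

oracle_point_triangle_dist <- function(p, a, b, c) {
  n <- needleplan:::cross3(b - a, c - a)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-14) { # degenerate triangle: fall back to edges
    return(min(oracle_point_segment_dist(p, a, b),
               oracle_point_segment_dist(p, b, c),
               oracle_point_segment_dist(p, c, a)))
  }
  n <- n / nn
  dplane <- sum((p - a) * n)
  q <- p - dplane * n
  # barycentric coordinates of the projection
  v0 <- b - a; v1 <- c - a; v2 <- q - a
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01 * d01
  v <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  u <- 1 - v - w
  if (u >= 0 && v >= 0 && w >= 0) return(abs(dplane))
  min(oracle_point_segment_dist(p, a, b),
      oracle_point_segment_dist(p, b, c),
      oracle_point_segment_dist(p, c, a))
}

oracle_segment_mesh_dist <- function(p0, p1, mesh) {
  d <- p1 - p0
  best <- Inf
  for (i in seq_len(nrow(mesh$faces))) {
    a <- mesh$vertices[mesh$faces[i, 1], ]
    b <- mesh$vertices[mesh$faces[i, 2], ]
    cc <- mesh$vertices[mesh$faces[i, 3], ]
    f <- function(t) oracle_point_triangle_dist(p0 + t * d, a, b, cc)
    opt <- stats::optimize(f, c(0, 1), tol = 1e-10)$objective
    best <- min(best, opt, f(0), f(1))
  }
  best
}

# Small random triangle-soup mesh (not closed; fine for distance queries).
random_soup_mesh <- function(n_tri = 6, scale = 10) {
  verts <- matrix(stats::runif(9 * n_tri, -scale, scale), ncol = 3)
  triangle_mesh(verts, matrix(seq_len(3 * n_tri), ncol = 3, byrow = TRUE),
                label = "soup")
}

# A single large triangle lying in the plane x = x0 (exact analytic
# distance x0 from the z-axis).
plane_triangle_at_x <- function(x0, half = 200) {
  triangle_mesh(rbind(c(x0, -half, -half), c(x0, half, -half),
                      c(x0, 0, half)),
                rbind(c(1, 2, 3)), label = "wall")
}
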