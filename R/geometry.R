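# Low-level planar geometry shared by the segmentation, landmark and
# template-mapping stages. All coordinates are 0-based (x, y), origin at
# the top-left pixel centre.

vec_norm <- function(v) sqrt(sum(v^2))

# 90-degree rotation; with y pointing down this turns the direction
# "towards the fingertips" into "towards the thumb side" consistently.
perp2 <- function(v) c(-v[2], v[1])

#' Signed polygon area (shoelace)
#' @param pts n x 2 matrix of polygon vertices in order.
#' @return signed area; positive for counter-clockwise order in a
#'   y-down frame.
#' @keywords internal
polygon_area_signed <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygon_area <- function(pts) abs(polygon_area_signed(pts))

# Vectorized even-odd point-in-polygon (ray crossing).
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py))
    if (any(crosses)) {
      xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  inside
}

# Crossing points of the line/ray with signed offset f at the polygon
# vertices (vectorized over edges). Shared workhorse of the two
# intersection helpers below.
polygon_line_crossings <- function(a, f, poly) {
  m <- nrow(poly)
  jn <- c(2:m, 1L)
  fi <- f; fj <- f[jn]
  cross <- ((fi > 0) != (fj > 0)) & (fi != fj)
  if (!any(cross)) return(NULL)
  i <- which(cross)
  s <- fi[i] / (fi[i] - fj[i])
  cbind(poly[i, 1] + s * (poly[jn[i], 1] - poly[i, 1]),
        poly[i, 2] + s * (poly[jn[i], 2] - poly[i, 2]))
}

# Intersections of the infinite line {p : dot(n, p - a) = 0} with the
# closed polygon boundary. Returns a matrix of crossing points plus the
# signed parameter of each along the line direction d (unit perp of n).
line_polygon_intersections <- function(a, n, poly) {
  d <- perp2(n)
  f <- (poly[, 1] - a[1]) * n[1] + (poly[, 2] - a[2]) * n[2]
  pts <- polygon_line_crossings(a, f, poly)
  if (is.null(pts)) return(list(points = matrix(numeric(0), 0, 2),
                                t = numeric(0)))
  ts <- (pts[, 1] - a[1]) * d[1] + (pts[, 2] - a[2]) * d[2]
  keep <- !duplicated(round(pts, 6))
  list(points = pts[keep, , drop = FALSE], t = ts[keep])
}

# First crossing of the ray a + t*dir (t > eps) with the polygon
# boundary; NULL if none.
ray_polygon_first_hit <- function(a, dir, poly, eps = 1e-9) {
  dir <- dir / vec_norm(dir)
  n <- perp2(dir)
  f <- (poly[, 1] - a[1]) * n[1] + (poly[, 2] - a[2]) * n[2]
  pts <- polygon_line_crossings(a, f, poly)
  if (is.null(pts)) return(NULL)
  t <- (pts[, 1] - a[1]) * dir[1] + (pts[, 2] - a[2]) * dir[2]
  ok <- t > eps
  if (!any(ok)) return(NULL)
  k <- which(ok)[which.min(t[ok])]
  list(point = pts[k, ], t = t[k])
}

# Boolean W x H matrix of pixel centres in the half-plane
# dot(n, p - a) >= 0.
halfplane_mask <- function(width, height, a, n) {
  x <- (seq_len(width) - 1) - a[1]
  y <- (seq_len(height) - 1) - a[2]
  outer(x * n[1], y * n[2], "+") >= 0
}

# Boolean W x H matrix of pixel centres inside a convex polygon given in
# consistent winding order (either orientation accepted).
convex_polygon_mask <- function(width, height, poly) {
  if (polygon_area_signed(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
  m <- matrix(TRUE, width, height)
  x <- seq_len(width) - 1
  y <- seq_len(height) - 1
  nv <- nrow(poly)
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    e <- poly[j, ] - poly[i, ]
    # interior of a positively-oriented polygon: cross(e, p - p_i) >= 0
    m <- m & (outer(-(x - poly[i, 1]) * e[2], (y - poly[i, 2]) * e[1], "+") >= 0)
    if (!any(m)) break
  }
  m
}

# TRUE when any three of the four corners are (near-)collinear, i.e. the
# quad cannot support a homography.
quad_degenerate <- function(pts, tol = 1e-7) {
  idx <- utils::combn(4, 3)
  scale2 <- max(dist(pts))^2
  if (!is.finite(scale2) || scale2 == 0) return(TRUE)
  for (k in seq_len(ncol(idx))) {
    p <- pts[idx[, k], ]
    a2 <- abs(polygon_area_signed(p))
    if (a2 < tol * scale2) return(TRUE)
  }
  FALSE
}

# Similarity transform helpers: pose = list(scale, theta, tx, ty),
# mapping canonical coordinates q to s * R(theta) q + t.
apply_pose <- function(pts, pose) {
  ct <- cos(pose$theta); st <- sin(pose$theta)
  x <- pts[, 1]; y <- pts[, 2]
  cbind(pose$scale * (ct * x - st * y) + pose$tx,
        pose$scale * (st * x + ct * y) + pose$ty)
}
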