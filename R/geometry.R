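# Internal planar-geometry helpers. All coordinates are 0-based pixel
# coordinates (x rightward, y downward, origin at the centre of the
# top-left pixel) unless stated otherwise.

#' Distance from points to a line segment
#'
#' @param pts numeric matrix with columns x, y (one row per point).
#' @param seg numeric matrix 2 x 2: rows are the segment endpoints.
#' @return numeric vector of Euclidean distances.
#' @noRd
dist_to_segment <- function(pts, seg) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  a <- as.numeric(seg[1, ])
  b <- as.numeric(seg[2, ])
  ab <- b - a
  len2 <- sum(ab^2)
  dx <- pts[, 1] - a[1]
  dy <- pts[, 2] - a[2]
  if (len2 == 0) {
    return(sqrt(dx^2 + dy^2))
  }
  t <- pmin(1, pmax(0, (dx * ab[1] + dy * ab[2]) / len2))
  px <- a[1] + t * ab[1]
  py <- a[2] + t * ab[2]
  sqrt((pts[, 1] - px)^2 + (pts[, 2] - py)^2)
}

#' Minimum distance between two segments
#' @noRd
segment_segment_distance <- function(seg1, seg2) {
  # sampled endpoints + mutual point-segment distances; exact for the
  # non-intersecting case used in config validation
  d <- c(
    dist_to_segment(seg1, seg2),
    dist_to_segment(seg2, seg1)
  )
  if (segments_intersect(seg1, seg2)) 0 else min(d)
}

#' @noRd
segments_intersect <- function(seg1, seg2) {
  o <- function(p, q, r) {
    sign((q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1]))
  }
  p1 <- seg1[1, ]; p2 <- seg1[2, ]; p3 <- seg2[1, ]; p4 <- seg2[2, ]
  o1 <- o(p1, p2, p3); o2 <- o(p1, p2, p4)
  o3 <- o(p3, p4, p1); o4 <- o(p3, p4, p2)
  (o1 != o2 && o3 != o4) ||
    (o1 == 0 && on_segment(p1, p2, p3)) ||
    (o2 == 0 && on_segment(p1, p2, p4)) ||
    (o3 == 0 && on_segment(p3, p4, p1)) ||
    (o4 == 0 && on_segment(p3, p4, p2))
}

#' @noRd
on_segment <- function(p, q, r) {
  r[1] >= min(p[1], q[1]) - 1e-9 && r[1] <= max(p[1], q[1]) + 1e-9 &&
    r[2] >= min(p[2], q[2]) - 1e-9 && r[2] <= max(p[2], q[2]) + 1e-9
}

#' Point-in-polygon test (TRUE for interior points; edge points are
#' resolved by the underlying even-odd rule)
#'
#' @param pts matrix with columns x, y.
#' @param poly matrix with columns x, y (vertices, not closed).
#' @noRd
points_in_polygon <- function(pts, poly) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  mgcv::in.out(rbind(as.matrix(poly), as.matrix(poly)[1, , drop = FALSE]),
               pts)
}

#' Sample the boundary of an ellipse as a polygon
#'
#' @param center length-2 numeric (x, y).
#' @param semi_axes length-2 numeric (major, minor), px.
#' @param theta orientation of the major axis, radians, measured from the
#'   +x axis toward +y (downward).
#' @param n number of boundary points.
#' @noRd
ellipse_polygon <- function(center, semi_axes, theta, n = 72L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  ct <- cos(theta); st <- sin(theta)
  ex <- semi_axes[1] * cos(t)
  ey <- semi_axes[2] * sin(t)
  cbind(
    x = center[1] + ex * ct - ey * st,
    y = center[2] + ex * st + ey * ct
  )
}

#' Axis-aligned rectangle as a 4-vertex polygon
#' @param rect named numeric: x0, y0, width, height.
#' @noRd
rect_polygon <- function(rect) {
  cbind(
    x = rect[["x0"]] + c(0, rect[["width"]], rect[["width"]], 0),
    y = rect[["y0"]] + c(0, 0, rect[["height"]], rect[["height"]])
  )
}
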