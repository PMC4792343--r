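# Low-level planar geometry helpers shared by the mesh, mechanics and metrics
# code.  All routines are vectorised over matrix rows where it matters.

#' Signed polygon area (shoelace formula)
#'
#' @param xy two-column matrix of vertices in order; the polygon is closed
#'   implicitly (last vertex connects back to the first).
#' @return signed area, positive for counter-clockwise orientation.
#' @keywords internal
shoelace_area <- function(xy) {
  n <- nrow(xy)
  if (n < 3L) return(0)
  x <- xy[, 1L]; y <- xy[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  0.5 * sum(x * yn - xn * y)
}

#' Polygon centroid (area-weighted)
#' @keywords internal
polygon_centroid <- function(xy) {
  n <- nrow(xy)
  x <- xy[, 1L]; y <- xy[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- 0.5 * sum(cr)
  if (abs(a) < 1e-300) return(colMeans(xy))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Segment lengths along a polyline
#' @param xy two-column matrix of chain vertices.
#' @return numeric vector of length nrow(xy) - 1.
#' @keywords internal
chain_seg_lengths <- function(xy) {
  n <- nrow(xy)
  dx <- xy[-1L, 1L] - xy[-n, 1L]
  dy <- xy[-1L, 2L] - xy[-n, 2L]
  sqrt(dx * dx + dy * dy)
}

#' Total polyline length
#' @keywords internal
chain_length <- function(xy) sum(chain_seg_lengths(xy))

#' Clip a convex polygon by the half-plane a.x <= b (Sutherland-Hodgman step)
#'
#' @param xy CCW convex polygon vertices.
#' @param a length-2 normal vector; @param b offset.
#' @return clipped polygon (possibly with 0 rows).
#' @keywords internal
clip_halfplane <- function(xy, a, b) {
  n <- nrow(xy)
  if (n == 0L) return(xy)
  d <- xy %*% a - b          # >0 means outside
  inside <- d <= 0
  if (all(inside)) return(xy)
  if (!any(inside)) return(xy[0L, , drop = FALSE])
  out <- matrix(0, n + 4L, 2L)
  m <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (inside[i]) { m <- m + 1L; out[m, ] <- xy[i, ] }
    if (inside[i] != inside[j]) {
      t <- d[i] / (d[i] - d[j])
      m <- m + 1L
      out[m, ] <- xy[i, ] + t * (xy[j, ] - xy[i, ])
    }
  }
  out[seq_len(m), , drop = FALSE]
}

#' Regular n-gon used as the convex clip region for tessellations
#' @keywords internal
regular_ngon <- function(n, radius, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1L] + radius * cos(th), center[2L] + radius * sin(th))
}

#' Angle of a 2-vector in [0, 2*pi)
#' @keywords internal
vec_angle <- function(v) {
  a <- atan2(v[2L], v[1L])
  if (a < 0) a <- a + 2 * pi
  a
}

#' Interior angle between two direction vectors, in radians [0, 2*pi)
#' measured counter-clockwise from \code{v1} to \code{v2}.
#' @keywords internal
ccw_angle <- function(v1, v2) {
  a <- atan2(v2[2L], v2[1L]) - atan2(v1[2L], v1[1L])
  if (a < 0) a <- a + 2 * pi
  a
}
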