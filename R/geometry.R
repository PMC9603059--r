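# Planar polygon primitives used by the hexagonal tessellation.
# All coordinates are assumed to lie in a projected (planar) CRS.

# Signed shoelace area; vertices as two-column matrix, open ring (no repeat).
polygon_signed_area <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygon_area <- function(xy) abs(polygon_signed_area(xy))

# Ensure counter-clockwise orientation.
polygon_ccw <- function(xy) {
  if (polygon_signed_area(xy) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE] else xy
}

# Sutherland-Hodgman clip of an arbitrary simple polygon `subject` against a
# convex polygon `clipper` (both open rings, CCW). Returns the clipped ring;
# may contain degenerate zero-area bridges for non-convex subjects, which do
# not affect the shoelace area.
clip_polygon_convex <- function(subject, clipper) {
  clipper <- polygon_ccw(clipper)
  out <- polygon_ccw(subject)
  nc <- nrow(clipper)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0) break
    a <- clipper[i, ]
    b <- clipper[if (i == nc) 1 else i + 1, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    # inside = left of directed edge a->b (CCW clipper)
    side <- ex * (out[, 2] - a[2]) - ey * (out[, 1] - a[1])
    n <- nrow(out)
    nxt <- c(2:n, 1)[seq_len(n)]
    keep_x <- numeric(0); keep_y <- numeric(0)
    for (k in seq_len(n)) {
      j <- nxt[k]
      cur_in <- side[k] >= 0
      nxt_in <- side[j] >= 0
      if (cur_in) {
        keep_x <- c(keep_x, out[k, 1]); keep_y <- c(keep_y, out[k, 2])
      }
      if (xor(cur_in, nxt_in)) {
        t <- side[k] / (side[k] - side[j])
        keep_x <- c(keep_x, out[k, 1] + t * (out[j, 1] - out[k, 1]))
        keep_y <- c(keep_y, out[k, 2] + t * (out[j, 2] - out[k, 2]))
      }
    }
    out <- cbind(keep_x, keep_y)
  }
  out
}

# Area of intersection between a polygon (list of disjoint parts) and a convex
# polygon.
intersection_area_convex <- function(parts, convex) {
  sum(vapply(parts, function(p) {
    clipped <- clip_polygon_convex(p, convex)
    if (nrow(clipped) < 3) 0 else polygon_area(clipped)
  }, numeric(1)))
}

# Ray-casting point-in-polygon for a single ring (even-odd rule).
point_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    crosses <- ((y[i] > py) != (yn[i] > py))
    if (any(crosses)) {
      xint <- x[i] + (py[crosses] - y[i]) / (yn[i] - y[i]) * (xn[i] - x[i])
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
    }
  }
  inside
}
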