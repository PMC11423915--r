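# Internal planar-geometry primitives shared by the morphometry modules.
# All coordinates are micrometres in a right-handed frame (+y up).

# Absolute tolerance for geometric predicates; far below hand-tracing
# precision (~0.1 um).
.GEOM_TOL <- 1e-9

# Signed area of a polygon given as an n x 2 matrix (shoelace formula).
# Positive for counter-clockwise orientation.
.signed_area <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

.perimeter <- function(v) {
  d <- rbind(v[-1L, , drop = FALSE], v[1L, , drop = FALSE]) - v
  sum(sqrt(rowSums(d^2)))
}

# Centroid and central second-order area moments of a polygon ring.
# Returns signed quantities so that rings of opposite orientation (holes)
# subtract correctly when summed.
.ring_moments <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cross <- x * yn - xn * y
  a <- sum(cross) / 2
  mx <- sum((x + xn) * cross) / 6
  my <- sum((y + yn) * cross) / 6
  # raw second moments about the origin
  sxx <- sum((x^2 + x * xn + xn^2) * cross) / 12
  syy <- sum((y^2 + y * yn + yn^2) * cross) / 12
  sxy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cross) / 24
  list(area = a, mx = mx, my = my, sxx = sxx, syy = syy, sxy = sxy)
}

# Test whether a polygon is simple (no proper self-intersection and no
# touching of non-adjacent edges).  O(n^2) segment pair test; contours are
# small (typically < 100 vertices).
.is_simple_polygon <- function(v, tol = .GEOM_TOL) {
  n <- nrow(v)
  if (n < 3L) return(FALSE)
  p1 <- v
  p2 <- rbind(v[-1L, , drop = FALSE], v[1L, , drop = FALSE])
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # skip adjacent edges (they share one endpoint by construction)
      if (j == i + 1L || (i == 1L && j == n)) next
      if (.segments_cross(p1[i, ], p2[i, ], p1[j, ], p2[j, ], tol)) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# Do segments [a1,a2] and [b1,b2] intersect (including touching)?
.segments_cross <- function(a1, a2, b1, b2, tol = .GEOM_TOL) {
  d1 <- .orient(b1, b2, a1)
  d2 <- .orient(b1, b2, a2)
  d3 <- .orient(a1, a2, b1)
  d4 <- .orient(a1, a2, b2)
  if (((d1 > tol && d2 < -tol) || (d1 < -tol && d2 > tol)) &&
      ((d3 > tol && d4 < -tol) || (d3 < -tol && d4 > tol))) {
    return(TRUE)
  }
  if (abs(d1) <= tol && .on_segment(b1, b2, a1, tol)) return(TRUE)
  if (abs(d2) <= tol && .on_segment(b1, b2, a2, tol)) return(TRUE)
  if (abs(d3) <= tol && .on_segment(a1, a2, b1, tol)) return(TRUE)
  if (abs(d4) <= tol && .on_segment(a1, a2, b2, tol)) return(TRUE)
  FALSE
}

.orient <- function(p, q, r) {
  (q[1L] - p[1L]) * (r[2L] - p[2L]) - (q[2L] - p[2L]) * (r[1L] - p[1L])
}

.on_segment <- function(p, q, r, tol = .GEOM_TOL) {
  r[1L] >= min(p[1L], q[1L]) - tol && r[1L] <= max(p[1L], q[1L]) + tol &&
    r[2L] >= min(p[2L], q[2L]) - tol && r[2L] <= max(p[2L], q[2L]) + tol
}

# Sutherland-Hodgman clipping of an arbitrary simple polygon against a
# CONVEX clip polygon (both n x 2, CCW).  Exact double-precision arithmetic;
# the output may contain degenerate joining edges for disconnected results,
# which cancel in the shoelace area.
.clip_polygon_convex <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0L) break
    a <- clip[i, ]
    b <- clip[if (i == nc) 1L else i + 1L, ]
    inp <- out
    n <- nrow(inp)
    out <- matrix(numeric(0), ncol = 2L)
    # signed distance to the (a,b) edge line; inside is left of a->b (CCW)
    side <- (b[1L] - a[1L]) * (inp[, 2L] - a[2L]) -
      (b[2L] - a[2L]) * (inp[, 1L] - a[1L])
    for (k in seq_len(n)) {
      k2 <- if (k == n) 1L else k + 1L
      cur_in <- side[k] >= -.GEOM_TOL
      nxt_in <- side[k2] >= -.GEOM_TOL
      if (cur_in) out <- rbind(out, inp[k, ])
      if (cur_in != nxt_in) {
        t <- side[k] / (side[k] - side[k2])
        out <- rbind(out, inp[k, ] + t * (inp[k2, ] - inp[k, ]))
      }
    }
  }
  out
}

# Union of t-intervals given as a 2-column matrix; returns total length,
# clamped to [lo, hi].
.interval_union_length <- function(iv, lo = 0, hi = 1) {
  if (is.null(iv) || nrow(iv) == 0L) return(0)
  iv[, 1L] <- pmax(iv[, 1L], lo)
  iv[, 2L] <- pmin(iv[, 2L], hi)
  iv <- iv[iv[, 2L] > iv[, 1L], , drop = FALSE]
  if (nrow(iv) == 0L) return(0)
  o <- order(iv[, 1L])
  iv <- iv[o, , drop = FALSE]
  total <- 0
  cur_lo <- iv[1L, 1L]; cur_hi <- iv[1L, 2L]
  if (nrow(iv) > 1L) {
    for (k in 2L:nrow(iv)) {
      if (iv[k, 1L] <= cur_hi) {
        cur_hi <- max(cur_hi, iv[k, 2L])
      } else {
        total <- total + (cur_hi - cur_lo)
        cur_lo <- iv[k, 1L]; cur_hi <- iv[k, 2L]
      }
    }
  }
  total + (cur_hi - cur_lo)
}

# Intersection of the parametric segment p + t*d, t in [0,1], with a convex
# region described implicitly; helpers below return t-intervals.

# t-interval where p + t*d lies inside the disk centred at c with radius r.
.seg_disk_interval <- function(p, d, c, r) {
  f <- p - c
  A <- sum(d^2)
  B <- 2 * sum(f * d)
  C <- sum(f^2) - r^2
  if (A < .GEOM_TOL^2) {
    if (C <= 0) return(matrix(c(0, 1), ncol = 2L)) else return(NULL)
  }
  disc <- B^2 - 4 * A * C
  if (disc < 0) return(NULL)
  s <- sqrt(disc)
  matrix(c((-B - s) / (2 * A), (-B + s) / (2 * A)), ncol = 2L)
}

# t-interval where p + t*d lies inside the rectangle (slab) of half-width r
# around segment [q0, q1]: |perp dist| <= r and axial projection in [0, L].
.seg_slab_interval <- function(p, d, q0, q1, r) {
  e <- q1 - q0
  L <- sqrt(sum(e^2))
  if (L < .GEOM_TOL) return(NULL)
  u <- e / L                       # axial unit vector
  nvec <- c(-u[2L], u[1L])         # normal
  # coordinates of the moving point in the (u, n) frame anchored at q0
  a0 <- sum((p - q0) * u);  a1 <- sum(d * u)
  b0 <- sum((p - q0) * nvec); b1 <- sum(d * nvec)
  lo <- 0; hi <- 1
  clip1d <- function(c0, c1, lim_lo, lim_hi, lo, hi) {
    # keep t with lim_lo <= c0 + t*c1 <= lim_hi
    if (abs(c1) < .GEOM_TOL) {
      if (c0 < lim_lo || c0 > lim_hi) return(NULL)
      return(c(lo, hi))
    }
    t1 <- (lim_lo - c0) / c1
    t2 <- (lim_hi - c0) / c1
    c(max(lo, min(t1, t2)), min(hi, max(t1, t2)))
  }
  ax <- clip1d(a0, a1, 0, L, lo, hi)
  if (is.null(ax)) return(NULL)
  nr <- clip1d(b0, b1, -r, r, ax[1L], ax[2L])
  if (is.null(nr) || nr[1L] >= nr[2L]) return(NULL)
  matrix(nr, ncol = 2L)
}

# Vectorised even-odd point-in-polygon test (used by heatmaps and masks).
.points_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1L]; yi <- v[i, 2L]
    xj <- v[j, 1L]; yj <- v[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
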