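# Planar geometry primitives shared by the contour, meshing and fixture code.

# Signed twice-area of triangle (a, b, c); positive when counter-clockwise.
orient2d <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

# Do segments p1-p2 and p3-p4 intersect?  proper = TRUE demands a crossing
# in the strict interiors of both segments.
segments_intersect <- function(p1, p2, p3, p4, proper = FALSE) {
  d1 <- orient2d(p3[1], p3[2], p4[1], p4[2], p1[1], p1[2])
  d2 <- orient2d(p3[1], p3[2], p4[1], p4[2], p2[1], p2[2])
  d3 <- orient2d(p1[1], p1[2], p2[1], p2[2], p3[1], p3[2])
  d4 <- orient2d(p1[1], p1[2], p2[1], p2[2], p4[1], p4[2])
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
    return(TRUE)
  }
  if (proper) return(FALSE)
  on_seg <- function(a, b, c) {
    # c collinear with a-b and within the bounding box
    min(a[1], b[1]) - 1e-12 <= c[1] && c[1] <= max(a[1], b[1]) + 1e-12 &&
      min(a[2], b[2]) - 1e-12 <= c[2] && c[2] <= max(a[2], b[2]) + 1e-12
  }
  (d1 == 0 && on_seg(p3, p4, p1)) ||
    (d2 == 0 && on_seg(p3, p4, p2)) ||
    (d3 == 0 && on_seg(p1, p2, p3)) ||
    (d4 == 0 && on_seg(p1, p2, p4))
}

# Is the closed polygon (rows of P, implicitly closed) simple?
# O(n^2) pairwise test; adjacent segments may share only their endpoint.
polygon_is_simple <- function(P) {
  n <- nrow(P)
  if (n < 3) return(FALSE)
  nxt <- c(seq_len(n)[-1], 1L)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      adjacent <- (j == i + 1) || (i == 1 && j == n)
      if (adjacent) {
        # neighbours must cross only at the shared endpoint
        if (segments_intersect(P[i, ], P[nxt[i], ], P[j, ], P[nxt[j], ],
                               proper = TRUE)) {
          return(FALSE)
        }
      } else if (segments_intersect(P[i, ], P[nxt[i], ], P[j, ], P[nxt[j], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

polygon_signed_area <- function(P) {
  n <- nrow(P)
  x <- P[, 1]
  y <- P[, 2]
  xn <- x[c(2:n, 1)]
  yn <- y[c(2:n, 1)]
  sum(x * yn - xn * y) / 2
}

# Even-odd (ray crossing) point-in-polygon test, vectorized over query points.
points_in_polygon <- function(px, py, P) {
  n <- nrow(P)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- P[i, 1]; yi <- P[i, 2]
    xj <- P[j, 1]; yj <- P[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Distance from each query point to segment a-b (vectorized over points).
dist_points_segment <- function(px, py, a, b) {
  dx <- b[1] - a[1]
  dy <- b[2] - a[2]
  l2 <- dx * dx + dy * dy
  if (l2 == 0) {
    return(sqrt((px - a[1])^2 + (py - a[2])^2))
  }
  t <- pmin(1, pmax(0, ((px - a[1]) * dx + (py - a[2]) * dy) / l2))
  sqrt((px - (a[1] + t * dx))^2 + (py - (a[2] + t * dy))^2)
}

# Minimum distance from each query point to the closed polygon boundary.
dist_points_polygon <- function(px, py, P) {
  n <- nrow(P)
  d <- rep(Inf, length(px))
  j <- n
  for (i in seq_len(n)) {
    d <- pmin(d, dist_points_segment(px, py, P[j, ], P[i, ]))
    j <- i
  }
  d
}
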