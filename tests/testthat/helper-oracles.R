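# Independent brute-force oracles and hand-built fixtures. These deliberately
# avoid the package's own geometry helpers so they can serve as cross-checks.

oracle_cross <- function(o, a, b) {
  (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
}

# proper crossing of open segments p1-p2 and p3-p4
oracle_segments_cross <- function(p1, p2, p3, p4) {
  d1 <- oracle_cross(p3, p4, p1)
  d2 <- oracle_cross(p3, p4, p2)
  d3 <- oracle_cross(p1, p2, p3)
  d4 <- oracle_cross(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

# all-pairs segment test over a closed polygon (proper crossings only)
oracle_polygon_simple <- function(P) {
  n <- nrow(P)
  nxt <- c(seq_len(n)[-1], 1L)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i + 1 || (i == 1 && j == n)) next
      if (oracle_segments_cross(P[i, ], P[nxt[i], ], P[j, ], P[nxt[j], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

oracle_polygon_area <- function(P) {
  n <- nrow(P)
  i2 <- c(2:n, 1)
  abs(sum(P[, 1] * P[i2, 2] - P[i2, 1] * P[, 2])) / 2
}

# circumcircle via 2x2 linear solve (different route from the package's
# closed-form determinant expressions)
oracle_circumcircle <- function(a, b, c) {
  A <- rbind(2 * (b - a), 2 * (c - a))
  rhs <- c(sum(b^2) - sum(a^2), sum(c^2) - sum(a^2))
  if (abs(det(A)) < 1e-14) return(NULL)
  ctr <- solve(A, rhs)
  list(center = ctr, r2 = sum((a - ctr)^2))
}

# Brute-force Delaunay construction: every triple of points whose (strict)
# circumcircle contains no other point. Returns sorted "i-j-k" keys.
oracle_delaunay_triples <- function(pts, tol = 1e-9) {
  n <- nrow(pts)
  keys <- character(0)
  for (i in 1:(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      for (k in (j + 1):n) {
        cc <- oracle_circumcircle(pts[i, ], pts[j, ], pts[k, ])
        if (is.null(cc)) next
        d2 <- (pts[, 1] - cc$center[1])^2 + (pts[, 2] - cc$center[2])^2
        d2[c(i, j, k)] <- Inf
        if (all(d2 >= cc$r2 * (1 - tol))) {
          keys <- c(keys, paste(sort(c(i, j, k)), collapse = "-"))
        }
      }
    }
  }
  sort(keys)
}

tri_keys <- function(tris) {
  sort(apply(tris, 1, function(r) paste(sort(r), collapse = "-")))
}

# random points in convex position (convex hull of a uniform cloud)
random_convex_polygon <- function(n_cloud, seed) {
  set.seed(seed)
  pts <- matrix(stats::runif(2 * n_cloud), ncol = 2)
  hull <- rev(grDevices::chull(pts))
  pts[hull, , drop = FALSE]
}

unit_square_mesh <- function() {
  tri_mesh(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
           rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
}

# Strip mesh mirror-symmetric about the x axis: spine vertices on y = 0,
# one fan of triangles above and its exact mirror below.
symmetric_strip_mesh <- function(nseg = 4) {
  spine <- cbind(0:nseg, 0)
  top <- cbind((0:(nseg - 1)) + 0.5, 1)
  bot <- cbind((0:(nseg - 1)) + 0.5, -1)
  V <- rbind(spine, top, bot)
  tris <- NULL
  for (i in seq_len(nseg)) {
    a <- i
    b <- i + 1L
    t <- nseg + 1L + i
    bo <- 2L * nseg + 1L + i
    tris <- rbind(tris, c(a, b, t), c(a, bo, b))
  }
  tri_mesh(V, tris)
}

maple_fixture_mesh <- function(target_edge = 0.15) {
  kp <- make_outline("maple", n_keypoints = 24, seed = 7)
  mesh <- triangulate(sample_curve(fit_closed_bspline(kp), 48))
  list(keypoints = kp,
       mesh = optimize_mesh(mesh, iterations = 40, target_edge = target_edge))
}
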