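test_that("convex polygons triangulate to n-2 triangles covering their area", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  m <- triangulate(sq)
  expect_equal(nrow(m$triangles), 2L)
  expect_equal(mesh_area(m), 1)

  for (seed in 1:6) {
    poly <- random_convex_polygon(10 + 5 * seed, seed)
    m <- triangulate(poly)
    expect_equal(nrow(m$triangles), nrow(poly) - 2L)
    expect_lt(abs(mesh_area(m) - oracle_polygon_area(poly)), 1e-9)
    expect_true(all(m$boundary))
  }
})

test_that("triangulations of convex point sets match the brute-force
           empty-circumcircle construction", {
  for (seed in c(11, 12, 13)) {
    poly <- random_convex_polygon(60, seed)  # hull has well under 50 points
    m <- triangulate(poly)
    expect_identical(tri_keys(m$triangles), oracle_delaunay_triples(poly))
    # every output circumcircle is empty of all other vertices
    for (r in seq_len(nrow(m$triangles))) {
      tr <- m$triangles[r, ]
      cc <- oracle_circumcircle(poly[tr[1], ], poly[tr[2], ], poly[tr[3], ])
      d2 <- (poly[, 1] - cc$center[1])^2 + (poly[, 2] - cc$center[2])^2
      d2[tr] <- Inf
      expect_true(all(d2 >= cc$r2 * (1 - 1e-9)))
    }
  }
})

test_that("non-convex leaf polygons triangulate to exactly their interior", {
  kp <- make_outline("maple", n_keypoints = 24, lobe_depth = 0.6, seed = 3)
  b <- sample_curve(fit_closed_bspline(kp), 60)
  m <- triangulate(b)
  expect_lt(abs(mesh_area(m) - oracle_polygon_area(b)), 1e-9)
  # every polygon edge is an edge of the mesh
  E <- mesh_edges(m)
  ekeys <- paste(E[, 1], E[, 2])
  n <- nrow(b)
  ring <- cbind(seq_len(n), c(2:n, 1L))
  rkeys <- paste(pmin(ring[, 1], ring[, 2]), pmax(ring[, 1], ring[, 2]))
  expect_true(all(rkeys %in% ekeys))
  # triangle centroids are inside the polygon
  tris <- m$triangles
  cx <- (b[tris[, 1], 1] + b[tris[, 2], 1] + b[tris[, 3], 1]) / 3
  cy <- (b[tris[, 1], 2] + b[tris[, 2], 2] + b[tris[, 3], 2]) / 3
  expect_true(all(sp_in <- leafcycle:::points_in_polygon(cx, cy, b)))
})

test_that("invalid boundaries are rejected", {
  expect_error(triangulate(rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))),
               "self-intersect")
  expect_error(triangulate(rbind(c(0, 0), c(1, 0), c(1, 1))), "n >= 4")
})

test_that("mesh quality metrics match hand computations", {
  eq <- tri_mesh(rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2)),
                 matrix(1:3, 1))
  q <- mesh_quality(eq)
  expect_equal(q$min_angle, 60, tolerance = 1e-9)
  expect_equal(q$edge_length_cv, 0, tolerance = 1e-12)

  iso <- tri_mesh(rbind(c(0, 0), c(1, 0), c(0, 1)), matrix(1:3, 1))
  expect_equal(mesh_quality(iso)$min_angle, 45, tolerance = 1e-9)

  sqm <- unit_square_mesh()
  lens <- c(1, 1, 1, 1, sqrt(2))
  expect_equal(mesh_quality(sqm)$edge_length_cv,
               stats::sd(lens) / mean(lens), tolerance = 1e-12)
  expect_equal(mesh_quality(sqm)$triangle_count, 2L)
})

test_that("optimization repairs the sliver fan without touching the boundary", {
  sf <- sliver_fan_mesh()
  q0 <- mesh_quality(sf)
  expect_lt(q0$min_angle, 5)

  opt <- optimize_mesh(sf, iterations = 40)
  q1 <- mesh_quality(opt)
  expect_gt(q1$min_angle, q0$min_angle)
  expect_lt(q1$edge_length_cv, q0$edge_length_cv)
  expect_identical(opt$vertices[opt$boundary, ], sf$vertices[sf$boundary, ])
  expect_lt(abs(mesh_area(opt) - mesh_area(sf)), 1e-9)

  expect_identical(optimize_mesh(sf, 0), sf)
})

test_that("minimum angle is non-decreasing across optimization passes", {
  m <- sliver_fan_mesh()
  prev <- mesh_quality(m)$min_angle
  for (i in 1:25) {
    m <- optimize_mesh(m, 1)
    cur <- mesh_quality(m)$min_angle
    expect_gte(cur, prev - 1e-9)
    prev <- cur
  }
})

test_that("optimization is idempotent at convergence", {
  sf <- sliver_fan_mesh()
  m1 <- optimize_mesh(sf, 160)
  m2 <- optimize_mesh(m1, 160)
  expect_lt(max(abs(m2$vertices - m1$vertices)), 1e-6)
})

test_that("interior refinement reaches the target median edge length", {
  kp <- make_outline("ellipse", a = 2, b = 1, n_keypoints = 24)
  mesh <- triangulate(sample_curve(fit_closed_bspline(kp), 40))
  opt <- optimize_mesh(mesh, 30, target_edge = 0.2)
  E <- mesh_edges(opt)
  V <- opt$vertices
  med <- stats::median(sqrt(rowSums((V[E[, 1], ] - V[E[, 2], ])^2)))
  expect_lte(med, 0.2)
  expect_gt(nrow(opt$vertices), nrow(mesh$vertices))
  expect_lt(abs(mesh_area(opt) - mesh_area(mesh)), 1e-9)
  # inserted vertices are interior; original boundary is untouched
  expect_identical(opt$vertices[seq_len(40), ], mesh$vertices)
  expect_false(any(opt$boundary[-seq_len(40)]))
})
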