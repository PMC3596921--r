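# Triangular leaf meshes: incremental-insertion Delaunay triangulation of
# the boundary polygon, constrained to the polygon edges, plus the two-step
# optimization loop (relocate vertices, modify connectivity) that removes
# long narrow triangles.

#' Triangular mesh of a leaf
#'
#' Container for a 2D triangulated leaf model. Triangles are stored
#' counter-clockwise; each vertex carries a boundary flag and texture
#' coordinates (uv) obtained by normalizing its position into the unit
#' square of the boundary bounding box.
#'
#' @param vertices n x 2 numeric matrix of vertex coordinates.
#' @param triangles m x 3 integer matrix of vertex indices (1-based). Rows
#'   with clockwise orientation are reordered; zero-area rows are an error.
#' @param boundary Logical vector flagging boundary vertices. Defaults to
#'   vertices incident to an edge used by only one triangle.
#' @param uv Optional n x 2 matrix of texture coordinates in `[0, 1]^2`.
#'   Defaults to bbox-normalized vertex positions.
#' @param constrained Optional k x 2 matrix of constrained (polygon) edges
#'   that connectivity optimization must never flip.
#' @param bbox Optional bounding box `c(xmin, xmax, ymin, ymax)` used for uv
#'   normalization; defaults to the vertex bounding box. Kept with the mesh
#'   so vertices inserted later get consistent uv.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, triangles, boundary = NULL, uv = NULL,
                     constrained = NULL, bbox = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 2 || !all(is.finite(vertices))) {
    stop("vertices must be a finite n x 2 matrix", call. = FALSE)
  }
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  dimnames(triangles) <- NULL
  if (ncol(triangles) != 3 || nrow(triangles) < 1) {
    stop("triangles must be an m x 3 index matrix", call. = FALSE)
  }
  n <- nrow(vertices)
  if (any(triangles < 1L) || any(triangles > n)) {
    stop("triangle indices out of range", call. = FALSE)
  }
  a2 <- tri_signed_areas(vertices, triangles)
  flip <- a2 < 0
  if (any(flip)) {
    triangles[flip, c(2, 3)] <- triangles[flip, c(3, 2)]
    a2[flip] <- -a2[flip]
  }
  if (any(a2 <= 0)) {
    stop("every triangle must have positive area", call. = FALSE)
  }
  et <- edge_table(triangles)
  if (any(et$count > 2L)) {
    stop("an undirected edge may belong to at most two triangles",
         call. = FALSE)
  }
  if (is.null(bbox)) {
    bbox <- c(range(vertices[, 1]), range(vertices[, 2]))
  }
  if (is.null(uv)) {
    uv <- uv_from_bbox(vertices, bbox)
  } else {
    uv <- as.matrix(uv)
    storage.mode(uv) <- "double"
    if (!all(dim(uv) == c(n, 2))) {
      stop("uv must be an n x 2 matrix", call. = FALSE)
    }
  }
  if (is.null(boundary)) {
    single <- et$edges[et$count == 1L, , drop = FALSE]
    boundary <- seq_len(n) %in% unique(as.vector(single))
  }
  if (length(boundary) != n) {
    stop("boundary flags must have one entry per vertex", call. = FALSE)
  }
  if (!is.null(constrained)) {
    constrained <- as.matrix(constrained)
    storage.mode(constrained) <- "integer"
  }
  structure(
    list(vertices = vertices, triangles = triangles,
         boundary = as.logical(boundary), uv = uv,
         constrained = constrained, bbox = bbox),
    class = "tri_mesh"
  )
}

uv_from_bbox <- function(vertices, bbox) {
  w <- max(bbox[2] - bbox[1], .Machine$double.eps)
  h <- max(bbox[4] - bbox[3], .Machine$double.eps)
  cbind((vertices[, 1] - bbox[1]) / w, (vertices[, 2] - bbox[3]) / h)
}

tri_signed_areas <- function(V, tris) {
  orient2d(V[tris[, 1], 1], V[tris[, 1], 2],
           V[tris[, 2], 1], V[tris[, 2], 2],
           V[tris[, 3], 1], V[tris[, 3], 2]) / 2
}

# Numeric undirected edge key; exact for vertex indices below 2^26.
EDGE_KEY_BASE <- 67108864
edge_key <- function(u, v) pmin(u, v) * EDGE_KEY_BASE + pmax(u, v)

# Unique undirected edges of a triangle list, with usage counts plus the
# half-edge expansion (one row per directed triangle edge).
edge_table <- function(tris) {
  m <- nrow(tris)
  e <- rbind(tris[, c(1, 2), drop = FALSE],
             tris[, c(2, 3), drop = FALSE],
             tris[, c(3, 1), drop = FALSE])
  key <- edge_key(e[, 1], e[, 2])
  first <- !duplicated(key)
  ukey <- key[first]
  idx <- match(key, ukey)
  count <- tabulate(idx, nbins = length(ukey))
  list(edges = cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))[first, , drop = FALSE],
       count = count, key = key, ukey = ukey, idx = idx,
       tri_of = rep(seq_len(m), 3L))
}

# Circumcircle (center, squared radius) per triangle row.
circumcircles <- function(V, tris) {
  ax <- V[tris[, 1], 1]; ay <- V[tris[, 1], 2]
  bx <- V[tris[, 2], 1]; by <- V[tris[, 2], 2]
  cx <- V[tris[, 3], 1]; cy <- V[tris[, 3], 2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  a2 <- ax^2 + ay^2
  b2 <- bx^2 + by^2
  c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  cbind(ux, uy, (ax - ux)^2 + (ay - uy)^2)
}

point_in_triangle_rows <- function(V, tris, p, eps = 1e-12) {
  d1 <- orient2d(V[tris[, 1], 1], V[tris[, 1], 2],
                 V[tris[, 2], 1], V[tris[, 2], 2], p[1], p[2])
  d2 <- orient2d(V[tris[, 2], 1], V[tris[, 2], 2],
                 V[tris[, 3], 1], V[tris[, 3], 2], p[1], p[2])
  d3 <- orient2d(V[tris[, 3], 1], V[tris[, 3], 2],
                 V[tris[, 1], 1], V[tris[, 1], 2], p[1], p[2])
  scale <- abs(d1) + abs(d2) + abs(d3)
  d1 >= -eps * scale & d2 >= -eps * scale & d3 >= -eps * scale
}

# Restrict a candidate Bowyer-Watson cavity to the edge-connected component
# containing triangle `seed`; guards against numerically spurious members.
connected_cavity <- function(tris, bad, seed) {
  keys <- matrix(edge_key(as.vector(tris[, c(1, 2, 3)]),
                          as.vector(tris[, c(2, 3, 1)])),
                 nrow = nrow(tris))
  badidx <- which(bad)
  keep <- rep(FALSE, nrow(tris))
  keep[seed] <- TRUE
  frontier <- seed
  while (length(frontier)) {
    fkeys <- unique(as.vector(keys[frontier, , drop = FALSE]))
    cand <- badidx[!keep[badidx]]
    if (!length(cand)) break
    touch <- cand[rowSums(matrix(keys[cand, , drop = FALSE] %in% fkeys,
                                 nrow = length(cand))) > 0]
    keep[touch] <- TRUE
    frontier <- touch
  }
  keep
}

#' Delaunay triangulation of a planar point set by incremental insertion
#'
#' Bowyer-Watson construction: points are inserted one at a time into a
#' super-triangle; for each insertion the triangles whose circumcircle
#' contains the point are removed and the resulting cavity is re-fanned from
#' the new point. Cocircular ties resolve by insertion order.
#'
#' @param points n x 2 matrix of distinct points, n >= 3.
#' @return m x 3 integer matrix of counter-clockwise triangles covering the
#'   convex hull of the points.
#' @export
delaunay <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  n <- nrow(points)
  if (n < 3 || ncol(points) != 2 || !all(is.finite(points))) {
    stop("points must be a finite n x 2 matrix with n >= 3", call. = FALSE)
  }
  if (anyDuplicated(points)) {
    stop("points must be distinct", call. = FALSE)
  }
  ctr <- colMeans(points)
  rad <- max(sqrt((points[, 1] - ctr[1])^2 + (points[, 2] - ctr[2])^2))
  R <- rad * 64 + 1
  sv <- rbind(ctr + c(0, 3 * R), ctr + c(-3 * R, -2 * R), ctr + c(3 * R, -2 * R))
  V <- rbind(sv, points)
  tris <- matrix(c(1L, 2L, 3L), 1, 3)
  if (tri_signed_areas(V, tris) < 0) tris <- tris[, c(1, 3, 2), drop = FALSE]
  cc <- circumcircles(V, tris)
  for (ip in seq_len(n) + 3L) {
    p <- V[ip, ]
    d2 <- (cc[, 1] - p[1])^2 + (cc[, 2] - p[2])^2
    bad <- d2 <= cc[, 3] * (1 + 1e-12)
    cont <- which(point_in_triangle_rows(V, tris, p))
    if (!length(cont)) {
      stop("numerical failure locating a point during insertion", call. = FALSE)
    }
    bad[cont[1]] <- TRUE
    bad <- connected_cavity(tris, bad, cont[1])
    badidx <- which(bad)
    half <- rbind(tris[badidx, c(1, 2), drop = FALSE],
                  tris[badidx, c(2, 3), drop = FALSE],
                  tris[badidx, c(3, 1), drop = FALSE])
    key <- edge_key(half[, 1], half[, 2])
    boundary_half <- half[!(key %in% key[duplicated(key)]), , drop = FALSE]
    newtris <- cbind(boundary_half, ip)
    storage.mode(newtris) <- "integer"
    if (any(tri_signed_areas(V, newtris) <= 0)) {
      stop("degenerate geometry during point insertion", call. = FALSE)
    }
    tris <- rbind(tris[-badidx, , drop = FALSE], newtris)
    cc <- rbind(cc[-badidx, , drop = FALSE], circumcircles(V, newtris))
  }
  keep <- tris[, 1] > 3L & tris[, 2] > 3L & tris[, 3] > 3L
  out <- tris[keep, , drop = FALSE] - 3L
  storage.mode(out) <- "integer"
  dimnames(out) <- NULL
  out
}

# Rows of `tris` adjacent to undirected edge (u, v).
edge_triangles <- function(tris, u, v) {
  kk <- edge_key(u, v)
  keys <- matrix(edge_key(as.vector(tris[, c(1, 2, 3)]),
                          as.vector(tris[, c(2, 3, 1)])),
                 nrow = nrow(tris))
  which(keys[, 1] == kk | keys[, 2] == kk | keys[, 3] == kk)
}

# Replace the two triangles sharing edge (u, v) by the flipped pair.
# Returns NULL when the edge is absent, boundary, or the quad is not convex.
try_flip_edge <- function(V, tris, u, v) {
  rows <- edge_triangles(tris, u, v)
  if (length(rows) != 2) return(NULL)
  cpt <- sum(tris[rows[1], ]) - u - v
  dpt <- sum(tris[rows[2], ]) - u - v
  if (!segments_intersect(V[u, ], V[v, ], V[cpt, ], V[dpt, ], proper = TRUE)) {
    return(NULL)
  }
  t1 <- c(cpt, dpt, u)
  t2 <- c(dpt, cpt, v)
  if (orient2d(V[t1[1], 1], V[t1[1], 2], V[t1[2], 1], V[t1[2], 2],
               V[t1[3], 1], V[t1[3], 2]) <= 0) t1 <- t1[c(1, 3, 2)]
  if (orient2d(V[t2[1], 1], V[t2[1], 2], V[t2[2], 1], V[t2[2], 2],
               V[t2[3], 1], V[t2[3], 2]) <= 0) t2 <- t2[c(1, 3, 2)]
  tris[rows[1], ] <- as.integer(t1)
  tris[rows[2], ] <- as.integer(t2)
  tris
}

has_edge <- function(tris, u, v) {
  kk <- edge_key(u, v)
  any(edge_key(as.vector(tris[, c(1, 2, 3)]),
               as.vector(tris[, c(2, 3, 1)])) == kk)
}

# Force polygon edge (a, b) into the triangulation by flipping the edges
# that cross segment a-b (classic constrained-Delaunay edge recovery).
recover_edge <- function(V, tris, a, b, max_iter = 1000L) {
  iter <- 0L
  while (!has_edge(tris, a, b)) {
    iter <- iter + 1L
    if (iter > max_iter) {
      stop("unable to recover a constrained boundary edge", call. = FALSE)
    }
    et <- edge_table(tris)
    E <- et$edges
    touches <- E[, 1] == a | E[, 1] == b | E[, 2] == a | E[, 2] == b
    cand <- which(!touches)
    crossing <- cand[vapply(cand, function(k) {
      segments_intersect(V[a, ], V[b, ], V[E[k, 1], ], V[E[k, 2], ],
                         proper = TRUE)
    }, logical(1))]
    if (!length(crossing)) {
      stop("constrained edge neither present nor recoverable", call. = FALSE)
    }
    progress <- FALSE
    for (k in crossing) {
      flipped <- try_flip_edge(V, tris, E[k, 1], E[k, 2])
      if (!is.null(flipped)) {
        tris <- flipped
        progress <- TRUE
        break
      }
    }
    if (!progress) {
      stop("edge recovery stalled on a non-convex edge fan", call. = FALSE)
    }
  }
  tris
}

#' Constrained Delaunay triangulation of a leaf boundary polygon
#'
#' Triangulates the interior of a simple closed polygon: the point set is
#' triangulated by incremental insertion ([delaunay()]), every polygon edge
#' is then enforced by edge recovery, and triangles outside the polygon are
#' culled. Boundary vertices are flagged and polygon edges recorded as
#' constrained so the optimizer never flips or moves them.
#'
#' @param boundary n x 2 matrix of polygon vertices in order (n >= 4), or a
#'   [key_point_set()]. Clockwise input is reversed to counter-clockwise.
#' @return A [tri_mesh()] covering exactly the polygon interior.
#' @export
triangulate <- function(boundary) {
  B <- if (inherits(boundary, "key_point_set")) boundary$points else {
    as.matrix(boundary)
  }
  storage.mode(B) <- "double"
  n <- nrow(B)
  if (n < 4 || ncol(B) != 2 || !all(is.finite(B))) {
    stop("boundary must be a finite n x 2 matrix with n >= 4", call. = FALSE)
  }
  if (!polygon_is_simple(B)) {
    stop("boundary polygon must not self-intersect", call. = FALSE)
  }
  if (polygon_signed_area(B) < 0) {
    B <- B[rev(seq_len(n)), , drop = FALSE]
  }
  tris <- delaunay(B)
  ring <- cbind(seq_len(n), c(2:n, 1L))
  for (k in seq_len(n)) {
    tris <- recover_edge(B, tris, ring[k, 1], ring[k, 2])
  }
  cx <- (B[tris[, 1], 1] + B[tris[, 2], 1] + B[tris[, 3], 1]) / 3
  cy <- (B[tris[, 1], 2] + B[tris[, 2], 2] + B[tris[, 3], 2]) / 3
  tris <- tris[points_in_polygon(cx, cy, B), , drop = FALSE]
  tri_mesh(B, tris, boundary = rep(TRUE, n), constrained = ring)
}

tri_min_angles_deg <- function(V, tris) {
  a <- V[tris[, 1], , drop = FALSE]
  b <- V[tris[, 2], , drop = FALSE]
  c <- V[tris[, 3], , drop = FALSE]
  la2 <- rowSums((b - c)^2)  # edge opposite vertex a
  lb2 <- rowSums((a - c)^2)
  lc2 <- rowSums((a - b)^2)
  ang <- function(o2, p2, q2) {
    acos(pmin(1, pmax(-1, (p2 + q2 - o2) / (2 * sqrt(p2 * q2)))))
  }
  deg <- 180 / pi
  pmin(ang(la2, lb2, lc2), ang(lb2, la2, lc2), ang(lc2, la2, lb2)) * deg
}

#' Mesh quality summary
#'
#' @param mesh A [tri_mesh()].
#' @return A list with `min_angle` (smallest interior angle over all
#'   triangles, degrees), `edge_length_cv` (sample standard deviation over
#'   mean of the unique edge lengths) and `triangle_count`.
#' @export
mesh_quality <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (nrow(mesh$triangles) == 0) {
    stop("mesh has no triangles", call. = FALSE)
  }
  V <- mesh$vertices
  tris <- mesh$triangles
  E <- edge_table(tris)$edges
  len <- sqrt(rowSums((V[E[, 1], , drop = FALSE] - V[E[, 2], , drop = FALSE])^2))
  cv <- if (length(len) > 1) stats::sd(len) / mean(len) else 0
  list(min_angle = min(tri_min_angles_deg(V, tris)),
       edge_length_cv = cv,
       triangle_count = nrow(tris))
}

locked_edge_keys <- function(tris, constrained) {
  et <- edge_table(tris)
  keys <- edge_key(et$edges[et$count == 1L, 1], et$edges[et$count == 1L, 2])
  if (!is.null(constrained)) {
    keys <- union(keys, edge_key(constrained[, 1], constrained[, 2]))
  }
  keys
}

# Lawson loop: flip non-constrained interior edges that violate the local
# empty-circumcircle criterion until none remain. One flip per scan keeps
# the adjacency bookkeeping simple; scans are vectorized.
flip_to_delaunay <- function(V, tris, locked, max_rounds = 500L) {
  for (round in seq_len(max_rounds)) {
    et <- edge_table(tris)
    inner <- which(et$count == 2L &
                     !(et$ukey %in% locked))
    if (!length(inner)) break
    # two adjacent triangle rows per inner edge
    ord <- order(et$idx)
    rows_sorted <- et$tri_of[ord]
    idx_sorted <- et$idx[ord]
    starts <- match(inner, idx_sorted)
    r1 <- rows_sorted[starts]
    r2 <- rows_sorted[starts + 1L]
    u <- et$edges[inner, 1]
    v <- et$edges[inner, 2]
    cpt <- as.integer(rowSums(tris[r1, , drop = FALSE]) - u - v)
    dpt <- as.integer(rowSums(tris[r2, , drop = FALSE]) - u - v)
    cc <- circumcircles(V, cbind(u, v, cpt))
    d2 <- (V[dpt, 1] - cc[, 1])^2 + (V[dpt, 2] - cc[, 2])^2
    violating <- which(d2 < cc[, 3] * (1 - 1e-12))
    flipped_any <- FALSE
    for (k in violating) {
      flipped <- try_flip_edge(V, tris, u[k], v[k])
      if (!is.null(flipped)) {
        tris <- flipped
        flipped_any <- TRUE
        break
      }
    }
    if (!flipped_any) break
  }
  tris
}

# Smart area-weighted Laplacian smoothing: an interior vertex moves toward
# the area-weighted centroid of its incident triangles, but a move is only
# accepted if no incident triangle inverts and the smallest incident angle
# does not decrease. This makes the per-pass minimum angle non-decreasing.
smooth_vertices <- function(V, tris, movable) {
  vt <- split(rep(seq_len(nrow(tris)), 3L), as.vector(tris))
  for (vid in which(movable)) {
    rows <- vt[[as.character(vid)]]
    if (is.null(rows)) next
    sub <- tris[rows, , drop = FALSE]
    cur_min <- min(tri_min_angles_deg(V, sub))
    A <- tri_signed_areas(V, sub)
    cxy <- cbind(
      (V[sub[, 1], 1] + V[sub[, 2], 1] + V[sub[, 3], 1]) / 3,
      (V[sub[, 1], 2] + V[sub[, 2], 2] + V[sub[, 3], 2]) / 3
    )
    target <- colSums(cxy * A) / sum(A)
    old <- V[vid, ]
    for (stepf in c(1, 0.5, 0.25)) {
      cand <- old + stepf * (target - old)
      V[vid, ] <- cand
      a2 <- tri_signed_areas(V, sub)
      if (all(a2 > 0) && min(tri_min_angles_deg(V, sub)) >= cur_min - 1e-12) {
        break
      }
      V[vid, ] <- old
    }
  }
  V
}

# Insert centroids of over-long triangles (longest edge > 1.5 * target)
# until the median unique edge length reaches the target.
refine_triangles <- function(V, tris, boundary, target_edge) {
  E <- edge_table(tris)$edges
  elen <- sqrt(rowSums((V[E[, 1], , drop = FALSE] - V[E[, 2], , drop = FALSE])^2))
  if (stats::median(elen) <= target_edge) {
    return(list(V = V, tris = tris, boundary = boundary))
  }
  l12 <- sqrt(rowSums((V[tris[, 1], , drop = FALSE] - V[tris[, 2], , drop = FALSE])^2))
  l23 <- sqrt(rowSums((V[tris[, 2], , drop = FALSE] - V[tris[, 3], , drop = FALSE])^2))
  l31 <- sqrt(rowSums((V[tris[, 3], , drop = FALSE] - V[tris[, 1], , drop = FALSE])^2))
  longest <- pmax(l12, l23, l31)
  flagged <- which(longest > 1.5 * target_edge)
  if (!length(flagged)) {
    # median still above target but no triangle passes the 1.5x rule:
    # split the longer half so refinement keeps converging on the target
    flagged <- which(longest > stats::median(elen))
  }
  for (r in flagged) {
    tri <- tris[r, ]
    p <- c(mean(V[tri, 1]), mean(V[tri, 2]))
    V <- rbind(V, p, deparse.level = 0)
    boundary <- c(boundary, FALSE)
    vid <- nrow(V)
    tris[r, ] <- as.integer(c(tri[1], tri[2], vid))
    tris <- rbind(tris,
                  as.integer(c(tri[2], tri[3], vid)),
                  as.integer(c(tri[3], tri[1], vid)))
  }
  list(V = V, tris = tris, boundary = boundary)
}

#' Optimize a leaf mesh into even-sized, well-shaped triangles
#'
#' Repeats the two-step improvement loop: (1) relocate each interior vertex
#' toward the area-weighted centroid of its incident triangles (a move is
#' rejected if it would invert a triangle or reduce the local minimum
#' angle); (2) modify connectivity by Delaunay edge flips. When
#' `target_edge` is given, centroids of triangles whose longest edge exceeds
#' 1.5 x `target_edge` are inserted each iteration until the median edge
#' length reaches the target. Boundary vertices and constrained polygon
#' edges are never touched.
#'
#' @param mesh A [tri_mesh()].
#' @param iterations Number of full passes (default 160).
#' @param target_edge Optional interior refinement edge-length target.
#' @return The optimized [tri_mesh()].
#' @export
optimize_mesh <- function(mesh, iterations = 160, target_edge = NULL) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (!is.numeric(iterations) || length(iterations) != 1 ||
      iterations < 0 || iterations != round(iterations)) {
    stop("iterations must be a non-negative integer", call. = FALSE)
  }
  if (iterations == 0) return(mesh)
  V <- mesh$vertices
  tris <- mesh$triangles
  boundary <- mesh$boundary
  locked <- locked_edge_keys(tris, mesh$constrained)
  for (it in seq_len(iterations)) {
    V <- smooth_vertices(V, tris, !boundary)
    tris <- flip_to_delaunay(V, tris, locked)
    if (!is.null(target_edge)) {
      ref <- refine_triangles(V, tris, boundary, target_edge)
      if (nrow(ref$V) > nrow(V)) {
        V <- ref$V
        tris <- ref$tris
        boundary <- ref$boundary
        tris <- flip_to_delaunay(V, tris, locked)
      }
    }
  }
  tri_mesh(V, tris, boundary = boundary, constrained = mesh$constrained,
           bbox = mesh$bbox)
}

#' Unique undirected edges of a mesh
#'
#' @param mesh A [tri_mesh()] (or a raw m x 3 triangle index matrix).
#' @return A two-column integer matrix of unique edges with `u < v`, with an
#'   attribute `count` giving the number of incident triangles per edge
#'   (1 = boundary edge, 2 = interior edge).
#' @export
mesh_edges <- function(mesh) {
  tris <- if (inherits(mesh, "tri_mesh")) mesh$triangles else mesh
  et <- edge_table(tris)
  structure(et$edges, count = et$count)
}

#' Total mesh area
#'
#' @param mesh A [tri_mesh()].
#' @return Sum of triangle areas.
#' @export
mesh_area <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  sum(tri_signed_areas(mesh$vertices, mesh$triangles))
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh: %d vertices (%d boundary), %d triangles>\n",
              nrow(x$vertices), sum(x$boundary), nrow(x$triangles)))
  invisible(x)
}
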