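# Procedural stand-ins for scanned inputs: leaf outlines with lobes, mask
# maps with dark edge / bright vein regions, default senescence specs, and a
# sliver-fan mesh used to exercise the mesh optimizer. All generators are
# pure functions of their parameters and seed.

#' Generate a synthetic leaf outline
#'
#' `ellipse` places key points exactly on an axis-aligned ellipse. `maple`
#' uses the polar lobe profile
#' `r(theta) = R * (1 - depth * |sin(lobes * theta / 2)|^sharpness)`,
#' scaled by `b/a` in y, which produces a closed, non-self-intersecting
#' lobed silhouette reminiscent of a maple leaf. Optional seeded radial
#' jitter (at most `jitter` as a fraction of the local radius) roughens the
#' outline.
#'
#' @param shape `"ellipse"` or `"maple"`.
#' @param a,b Semi-axes (default 2 and 1).
#' @param n_keypoints Number of key points (>= 8 for maple, default 32).
#' @param lobes Lobe count for the maple shape (default 5).
#' @param lobe_depth Lobe depth in `[0, 1)` (default 0.5).
#' @param sharpness Exponent shaping the lobe profile (default 1).
#' @param jitter Radial jitter fraction; defaults to 0 for the ellipse and
#'   0.02 for the maple shape.
#' @param seed Seed for the jitter stream (default 1).
#' @return A [key_point_set()] in counter-clockwise order.
#' @export
make_outline <- function(shape = c("ellipse", "maple"), a = 2, b = 1,
                         n_keypoints = 32, lobes = 5, lobe_depth = 0.5,
                         sharpness = 1, jitter = NULL, seed = 1) {
  shape <- match.arg(shape)
  if (!is.numeric(a) || !is.numeric(b) || a <= 0 || b <= 0) {
    stop("semi-axes a and b must be positive", call. = FALSE)
  }
  if (shape == "maple" && n_keypoints < 8) {
    stop("maple outlines need at least 8 key points", call. = FALSE)
  }
  if (n_keypoints < 4) {
    stop("at least 4 key points are required", call. = FALSE)
  }
  if (lobe_depth < 0 || lobe_depth >= 1) {
    stop("lobe_depth must lie in [0, 1)", call. = FALSE)
  }
  if (is.null(jitter)) jitter <- if (shape == "maple") 0.02 else 0
  if (jitter < 0 || jitter > 0.02) {
    stop("jitter must lie in [0, 0.02]", call. = FALSE)
  }
  n <- as.integer(n_keypoints)
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  r <- if (shape == "ellipse") {
    rep(1, n)
  } else {
    1 - lobe_depth * abs(sin(lobes * theta / 2))^sharpness
  }
  if (jitter > 0) {
    u <- hash_uniform(seed, seq_len(n), 0L)
    r <- r * (1 + jitter * (2 * u - 1))
  }
  pts <- cbind(a * r * cos(theta), b * r * sin(theta))
  key_point_set(pts)
}

#' Generate a synthetic grayscale mask map
#'
#' Emulates a hand-painted mask over the leaf region. Pixels outside the
#' boundary polygon are set to 255. Patterns: `uniform` paints every
#' interior pixel with `value`; `dark-edge` paints pixels within
#' `edge_band` of the boundary with `dark` and the rest with `bright`
#' (edge and corner regions then deform most); `bright-vein` paints pixels
#' within `vein_halfwidth` of the midrib (the segment joining the leftmost
#' and rightmost boundary points) with `bright` and everything else with
#' `dark` (the vein then stays put while the blade curls).
#'
#' Pixel (row, col) centers are mapped onto the boundary bounding box, so
#' mask lookups through bbox-normalized texture coordinates land on the
#' matching pixels. Distances are exact point-to-segment distances, not
#' raster approximations.
#'
#' @param pattern `"uniform"`, `"dark-edge"` or `"bright-vein"`.
#' @param boundary Boundary polygon (matrix or [key_point_set()]).
#' @param width,height Mask resolution in pixels (default 64 x 64).
#' @param value Interior value for the uniform pattern (default 128).
#' @param dark,bright Dark and bright paint values (defaults 16 and 200;
#'   dark must be less than bright).
#' @param edge_band Width of the dark edge band, in boundary coordinate
#'   units; defaults to 12 percent of the smaller bounding-box side.
#' @param vein_halfwidth Half-width of the vein corridor; defaults to 8
#'   percent of the smaller bounding-box side.
#' @return A [mask_map()].
#' @export
make_mask <- function(pattern = c("uniform", "dark-edge", "bright-vein"),
                      boundary, width = 64, height = 64, value = 128,
                      dark = 16, bright = 200, edge_band = NULL,
                      vein_halfwidth = NULL) {
  pattern <- match.arg(pattern)
  B <- if (inherits(boundary, "key_point_set")) boundary$points else as.matrix(boundary)
  if (nrow(B) < 3 || abs(polygon_signed_area(B)) < .Machine$double.eps) {
    stop("boundary polygon is degenerate", call. = FALSE)
  }
  if (dark >= bright) stop("dark value must be below bright value", call. = FALSE)
  width <- as.integer(width)
  height <- as.integer(height)
  bbox <- c(range(B[, 1]), range(B[, 2]))
  bw <- bbox[2] - bbox[1]
  bh <- bbox[4] - bbox[3]
  if (is.null(edge_band)) edge_band <- 0.12 * min(bw, bh)
  if (is.null(vein_halfwidth)) vein_halfwidth <- 0.08 * min(bw, bh)
  # world coordinates of pixel centers; row 1 = top of the image
  cx <- bbox[1] + (rep(seq_len(width), each = height) - 0.5) / width * bw
  cy <- bbox[3] + (height - rep(seq_len(height), width) + 0.5) / height * bh
  inside <- points_in_polygon(cx, cy, B)
  px <- rep(255L, width * height)
  if (pattern == "uniform") {
    px[inside] <- as.integer(value)
  } else if (pattern == "dark-edge") {
    d <- dist_points_polygon(cx, cy, B)
    px[inside] <- ifelse(d[inside] < edge_band, as.integer(dark),
                         as.integer(bright))
  } else {
    lo <- B[which.min(B[, 1]), ]
    hi <- B[which.max(B[, 1]), ]
    d <- dist_points_segment(cx, cy, lo, hi)
    px[inside] <- ifelse(d[inside] < vein_halfwidth, as.integer(bright),
                         as.integer(dark))
  }
  mask_map(matrix(px, nrow = height, ncol = width))
}

#' Generate a default feed-forward senescence specification
#'
#' Builds an `n_states`-state chain whose last state is absorbing (the
#' fallen leaf). Half-life corner constants are drawn uniformly in
#' `[5, 60]` time units; transition corner constants favor forward moves,
#' decaying geometrically (factor 0.6) with the number of states skipped and
#' scaled by a seeded factor in `[0.6, 1]`. Backward transitions are zero.
#'
#' @param n_states Number of states (>= 2).
#' @param seed Seed for the corner draws (default 1).
#' @return A [senescence_spec()].
#' @export
make_default_spec <- function(n_states, seed = 1) {
  if (!is.numeric(n_states) || n_states < 2) {
    stop("n_states must be at least 2", call. = FALSE)
  }
  n <- as.integer(n_states)
  names_ <- c(paste0("stage_", seq_len(n - 1L) - 1L), "fallen")
  tau <- matrix(5 + 55 * hash_uniform(seed, seq_len(n * 4L), 1L), n, 4)
  X <- array(0, dim = c(n, n, 4))
  draw <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      draw <- draw + 1L
      scale <- 0.6 + 0.4 * hash_uniform(seed, draw, 2L)
      X[i, j, ] <- 0.6^(j - i - 1L) * scale *
        (0.9 + 0.1 * hash_uniform(seed, draw, 3L + seq_len(4L)))
    }
  }
  senescence_spec(names_, tau, X, absorbing = "fallen")
}

#' Sliver-fan test mesh
#'
#' A unit square whose interior holds a row of closely spaced, almost
#' collinear points, producing a fan of long narrow triangles with aspect
#' ratio about `aspect` : 1. Used to exercise the mesh optimizer: the
#' boundary (the four square corners) is pinned while the interior points
#' are free to move.
#'
#' @param n_slivers Number of interior points (default 20).
#' @param aspect Approximate sliver aspect ratio (default 20).
#' @return A [tri_mesh()].
#' @export
sliver_fan_mesh <- function(n_slivers = 20, aspect = 20) {
  n <- as.integer(n_slivers)
  stopifnot(n >= 2, aspect > 1)
  corners <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  dx <- 0.5 / aspect
  xs <- 0.5 + (seq_len(n) - (n + 1) / 2) * dx
  if (min(xs) <= 0 || max(xs) >= 1) {
    stop("too many slivers for this aspect ratio", call. = FALSE)
  }
  ys <- 0.5 + 1e-3 * rep_len(c(1, -1), n)  # break exact collinearity
  pts <- rbind(corners, cbind(xs, ys))
  tris <- delaunay(pts)
  tri_mesh(pts, tris,
           boundary = c(rep(TRUE, 4), rep(FALSE, n)),
           constrained = cbind(1:4, c(2:4, 1L)))
}
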