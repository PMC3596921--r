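# Leaf boundary construction: a smooth closed curve through key points on
# the leaf edge, resampled into the point set handed to triangulation.

#' Ordered key points on a closed leaf boundary
#'
#' Validates a set of edge key points (as picked interactively on a scanned
#' leaf, or produced by [make_outline()]) and wraps it for downstream use.
#'
#' @param points Numeric matrix or data frame with two columns (x, y), in
#'   traversal order around the leaf. The polygon is implicitly closed.
#' @return An object of class `key_point_set` with elements `points`
#'   (n x 2 matrix) and `closed` (always `TRUE`).
#' @details At least 4 points are required; consecutive points (including
#'   last-to-first) must be distinct and the polygon through the points must
#'   not self-intersect.
#' @examples
#' kp <- key_point_set(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' @export
key_point_set <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2 || !all(is.finite(points))) {
    stop("key points must be a finite n x 2 matrix", call. = FALSE)
  }
  n <- nrow(points)
  if (n < 4) {
    stop("at least 4 key points are required", call. = FALSE)
  }
  nxt <- points[c(2:n, 1), , drop = FALSE]
  if (any(rowSums((points - nxt)^2) == 0)) {
    stop("consecutive key points must not coincide", call. = FALSE)
  }
  if (!polygon_is_simple(points)) {
    stop("key-point polygon must not self-intersect", call. = FALSE)
  }
  structure(list(points = points, closed = TRUE), class = "key_point_set")
}

as_points_matrix <- function(x) {
  if (inherits(x, "key_point_set")) x$points else key_point_set(x)$points
}

#' Fit a smooth closed curve through leaf-edge key points
#'
#' Builds a periodic interpolating cubic spline through the key points,
#' parameterized by chord length over `[0, 1)`. The curve passes through
#' every key point exactly (to floating-point accuracy) and is value- and
#' tangent-continuous across the closure.
#'
#' @param key_points A [key_point_set()] or an n x 2 coordinate matrix.
#' @return An object of class `closed_curve` with the spline evaluators, the
#'   parameter value assigned to each key point (`params`), and the key
#'   points themselves.
#' @seealso [curve_eval()], [sample_curve()]
#' @export
fit_closed_bspline <- function(key_points) {
  pts <- as_points_matrix(key_points)
  n <- nrow(pts)
  chord <- sqrt(rowSums((pts[c(2:n, 1), , drop = FALSE] - pts)^2))
  u <- c(0, cumsum(chord)) / sum(chord)
  fx <- stats::splinefun(u, c(pts[, 1], pts[1, 1]), method = "periodic")
  fy <- stats::splinefun(u, c(pts[, 2], pts[1, 2]), method = "periodic")
  structure(
    list(fx = fx, fy = fy, params = u[seq_len(n)], key_points = pts),
    class = "closed_curve"
  )
}

#' Evaluate a closed boundary curve
#'
#' @param curve A `closed_curve` from [fit_closed_bspline()].
#' @param u Numeric vector of curve parameters; values are taken modulo 1,
#'   so the curve is periodic.
#' @return A length(u) x 2 matrix of coordinates.
#' @export
curve_eval <- function(curve, u) {
  stopifnot(inherits(curve, "closed_curve"))
  u <- u %% 1
  cbind(curve$fx(u), curve$fy(u))
}

#' Sample a closed curve approximately uniformly in arc length
#'
#' Builds a cumulative arc-length table over 1024 chord segments and inverts
#' it to place `n` samples at (approximately) equal arc-length spacing. The
#' first sample is always `curve(0)`, i.e. the first key point.
#'
#' @param curve A `closed_curve`.
#' @param n Number of boundary samples (at least 4; default 64).
#' @return An n x 2 matrix of boundary points in traversal order.
#' @export
sample_curve <- function(curve, n = 64) {
  stopifnot(inherits(curve, "closed_curve"))
  if (!is.numeric(n) || length(n) != 1 || n < 4 || n != round(n)) {
    stop("n must be an integer >= 4", call. = FALSE)
  }
  n <- as.integer(n)
  m <- 1024L
  ug <- seq(0, 1, length.out = m + 1L)
  pg <- curve_eval(curve, ug)
  seg <- sqrt(rowSums((pg[-1, , drop = FALSE] - pg[-(m + 1L), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  targets <- s[m + 1L] * (seq_len(n) - 1L) / n
  us <- stats::approx(s, ug, xout = targets, ties = "ordered")$y
  out <- curve_eval(curve, us)
  if (anyDuplicated(out)) {
    stop("curve sampling produced duplicate points; increase n or check curve",
         call. = FALSE)
  }
  out
}

#' @export
print.key_point_set <- function(x, ...) {
  cat(sprintf("<key_point_set: %d points, closed>\n", nrow(x$points)))
  invisible(x)
}

#' @export
print.closed_curve <- function(x, ...) {
  cat(sprintf("<closed_curve: periodic cubic through %d key points>\n",
              nrow(x$key_points)))
  invisible(x)
}
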