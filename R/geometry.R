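#' Vector and point primitives
#'
#' Points and vectors are plain numeric vectors of length 2 or 3 in image
#' coordinates: origin top-left, x rightward, y downward, z increasing away
#' from the viewer (so a surface facing the camera has a normal with negative
#' z). Two-dimensional inputs behave as z = 0 in 3D operations. All geometry
#' is double precision; comparisons elsewhere in the package use an absolute
#' tolerance of 1e-9.
#'
#' @param x,y,z Coordinates. `z` defaults to 0.
#' @return `pt3()` returns a numeric vector `c(x, y, z)`.
#' @examples
#' euclidean_distance(pt3(0, 0), pt3(3, 4)) # 5
#' angle_between(c(1, 0, 0), c(0, 1, 0))  # pi / 2
#' @export
pt3 <- function(x, y, z = 0) {
  p <- c(as.numeric(x), as.numeric(y), as.numeric(z))
  if (!all(is.finite(p))) abort_invalid_input("point coordinates must be finite")
  p
}

# Pad a length-2 point/vector to length 3 (z = 0); validate finiteness.
as_p3 <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) == 2L) p <- c(p, 0)
  if (length(p) != 3L) {
    abort_invalid_input(sprintf("%s must have 2 or 3 coordinates, got %d", what, length(p)))
  }
  if (!all(is.finite(p))) abort_invalid_input(sprintf("%s has non-finite coordinates", what))
  p
}

vnorm <- function(v) sqrt(sum(v^2))

#' @rdname pt3
#' @param p,q Points (numeric vectors of length 2 or 3).
#' @return `euclidean_distance()` returns the nonnegative scalar `||p - q||`.
#' @export
euclidean_distance <- function(p, q) {
  vnorm(as_p3(p) - as_p3(q))
}

#' @rdname pt3
#' @param u,v Vectors (numeric, length 2 or 3); must be nonzero for
#'   `angle_between()`.
#' @return `angle_between()` returns the angle in radians, in `[0, pi]`. The
#'   cosine is clamped to `[-1, 1]` before `acos()` so parallel and
#'   antiparallel inputs cannot produce NaN from rounding.
#' @export
angle_between <- function(u, v) {
  u <- as_p3(u, "vector"); v <- as_p3(v, "vector")
  nu <- vnorm(u); nv <- vnorm(v)
  if (nu == 0 || nv == 0) abort_degenerate("angle_between() requires nonzero vectors")
  acos(max(-1, min(1, sum(u * v) / (nu * nv))))
}

#' @rdname pt3
#' @return `cross_product()` returns the 3D cross product `u x v`; parallel
#'   inputs yield the zero vector (the caller must check).
#' @export
cross_product <- function(u, v) {
  u <- as_p3(u, "vector"); v <- as_p3(v, "vector")
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' @rdname pt3
#' @return `midpoint()` returns the componentwise mean of `p` and `q`.
#' @export
midpoint <- function(p, q) {
  (as_p3(p) + as_p3(q)) / 2
}

#' @rdname pt3
#' @param origin,target Points defining the ray `origin -> target`.
#' @param distance Distance from `origin` along that ray; may exceed
#'   `||target - origin||` (extrapolation is allowed).
#' @return `point_along()` returns the point on the ray at `distance` from
#'   `origin`.
#' @export
point_along <- function(origin, target, distance) {
  origin <- as_p3(origin); target <- as_p3(target)
  if (!is.finite(distance)) abort_invalid_input("distance must be finite")
  d <- target - origin
  nd <- vnorm(d)
  if (nd == 0) abort_degenerate("point_along() requires origin != target")
  origin + distance * d / nd
}

#' @rdname pt3
#' @param t Unitless fraction (typically in `[0, 1]`; any finite value works).
#' @return `fraction_point()` returns `p + t * (q - p)`.
#' @export
fraction_point <- function(p, q, t) {
  if (!is.finite(t)) abort_invalid_input("fraction t must be finite")
  p <- as_p3(p); q <- as_p3(q)
  p + t * (q - p)
}
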