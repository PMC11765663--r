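#' Cylinder geometry
#'
#' Construct a cylinder parameterized by its radius, axis direction
#' (azimuth/elevation angles) and center. The length is carried for
#' simulation (it bounds the scanned extent) but never constrains fitting:
#' the fitted shape is the infinite cylinder, reduced to its cross-section
#' circle on the plane orthogonal to the axis.
#'
#' @param radius cylinder radius in meters, > 0.
#' @param azimuth axis azimuth angle in radians.
#' @param elevation axis elevation angle in radians (`pi/2` is the +z pole).
#' @param center numeric length-3 center of the cylinder, meters.
#' @param length cylinder length in meters (extent along the axis).
#' @return an object of class `"cylinder_geometry"` with fields `radius`,
#'   `azimuth`, `elevation`, `center`, `length` and the derived unit `axis`.
#' @examples
#' cyl <- cylinder_geometry(0.05, 0, pi / 2, c(0, 0, 0), 0.25)
#' cyl$axis  # (0, 0, 1)
#' @export
cylinder_geometry <- function(radius, azimuth = 0, elevation = pi / 2,
                              center = c(0, 0, 0), length = Inf) {
  stopifnot(is.numeric(radius), length(radius) == 1L, is.finite(radius))
  if (radius <= 0) stop("cylinder radius must be > 0")
  azimuth <- as.numeric(azimuth)[1]
  elevation <- as.numeric(elevation)[1]
  stopifnot(is.finite(azimuth), is.finite(elevation))
  center <- unname(as.numeric(center))
  stopifnot(length(center) == 3L, all(is.finite(center)))
  structure(
    list(radius = radius, azimuth = azimuth, elevation = elevation,
         center = center, length = length,
         axis = axis_vector(azimuth, elevation)),
    class = "cylinder_geometry")
}

#' @export
print.cylinder_geometry <- function(x, ...) {
  cat("Cylinder geometry\n")
  cat(sprintf("  radius : %.6g m\n", x$radius))
  cat(sprintf("  axis   : (%.4f, %.4f, %.4f)  [azimuth %.4f rad, elevation %.4f rad]\n",
              x$axis[1], x$axis[2], x$axis[3], x$azimuth, x$elevation))
  cat(sprintf("  center : (%.6g, %.6g, %.6g) m\n",
              x$center[1], x$center[2], x$center[3]))
  if (is.finite(x$length)) cat(sprintf("  length : %.6g m\n", x$length))
  invisible(x)
}

#' Axis direction from azimuth and elevation
#'
#' `axis_vector()` maps spherical angles to the unit axis direction
#' (cos(el)cos(az), cos(el)sin(az), sin(el)); `axis_angles()` is its inverse
#' (well-defined away from the poles).
#'
#' @param azimuth,elevation angles in radians.
#' @return unit numeric length-3 vector.
#' @export
axis_vector <- function(azimuth, elevation) {
  stopifnot(is.finite(azimuth), is.finite(elevation))
  c(cos(elevation) * cos(azimuth),
    cos(elevation) * sin(azimuth),
    sin(elevation))
}

#' @rdname axis_vector
#' @param v unit length-3 direction.
#' @return `axis_angles`: named vector `c(azimuth=, elevation=)`.
#' @export
axis_angles <- function(v) {
  v <- v / sqrt(sum(v^2))
  c(azimuth = atan2(v[2], v[1]), elevation = asin(max(-1, min(1, v[3]))))
}

# Orthonormal basis (e1, e2) of the plane orthogonal to unit axis v.
# Reference vector (0,0,1) unless the axis is nearly vertical
# (|v.z| > 0.9), then (0,1,0); e1 = normalize(ref x v), e2 = v x e1.
# For v = z this yields the identity basis e1=(1,0,0), e2=(0,1,0).
cross_section_basis <- function(v) {
  v <- v / sqrt(sum(v^2))
  ref <- if (abs(v[3]) > 0.9) c(0, 1, 0) else c(0, 0, 1)
  e1 <- cross3(ref, v)
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(v, e1)
  rbind(e1, e2, deparse.level = 0)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Project points or a Gaussian onto the cross-sectional plane
#'
#' Projects 3D points, or a 3D Gaussian (mean + covariance), onto the
#' orthonormal basis of the plane orthogonal to the cylinder axis. A
#' Gaussian is reduced by marginalizing along the axis: the mean is
#' projected orthogonally and the covariance becomes `B %*% Sigma %*% t(B)`
#' where `B` holds the two basis rows. Marginalization (not conditioning)
#' is the right reduction here because the expected distance from the 3D
#' distribution to a shape invariant along the axis equals the expectation
#' over the marginal; this dimensionality-reduction construction is the
#' package's own (documented) reading of the approach.
#'
#' @param x either an n-by-3 matrix / length-3 vector of points, or a list
#'   `list(mean=, cov=)` describing a trivariate Gaussian.
#' @param cyl a [cylinder_geometry()].
#' @return a 2-column matrix of plane coordinates, or `list(mean=, cov=)`
#'   with a length-2 mean and 2x2 covariance.
#' @export
project_to_cross_section <- function(x, cyl) {
  B <- cross_section_basis(cyl$axis)
  if (is.list(x) && !is.null(x$cov)) {
    S <- as.matrix(x$cov)
    check_spd(S, "input covariance")
    mu <- B %*% as.numeric(x$mean)
    list(mean = as.numeric(mu), cov = B %*% S %*% t(B))
  } else {
    x <- to_matrix3(x)
    x %*% t(B)
  }
}

#' Project a point onto the cylinder axis line
#'
#' @param x length-3 point or n-by-3 matrix.
#' @param cyl a [cylinder_geometry()].
#' @return point(s) on the axis line; the displacement to the input is
#'   orthogonal to the axis.
#' @export
project_onto_axis <- function(x, cyl) {
  v <- cyl$axis
  if (is.matrix(x)) {
    w <- sweep(x, 2, cyl$center)
    t <- as.numeric(w %*% v)
    sweep(outer(t, v), 2, cyl$center, "+")
  } else {
    x <- as.numeric(x)
    cyl$center + sum((x - cyl$center) * v) * v
  }
}

#' Tangent-line envelope of a circle
#'
#' Approximates a circle by `t` tangent lines with tangent points uniformly
#' spaced in angle (at angles `2*pi*k/t`, k = 0..t-1, measured from the
#' first basis vector of the plane). The envelope replaces the curved
#' circle by locally flat lines, which is what removes the curvature bias
#' of direct point-to-circle distances.
#'
#' @param center length-2 circle center.
#' @param radius circle radius, > 0.
#' @param t number of tangent lines, >= 3.
#' @return object of class `"tangent_envelope"`: a list with matrix
#'   `point` (t x 2, tangent points on the circle) and `normal` (t x 2,
#'   outward unit normals), plus `center` and `radius`.
#' @export
tangent_envelope <- function(center, radius, t) {
  stopifnot(radius > 0)
  if (t < 3) stop("envelope too small: need at least 3 tangent lines")
  center <- as.numeric(center)
  theta <- 2 * pi * (seq_len(t) - 1) / t
  n <- cbind(cos(theta), sin(theta))
  structure(
    list(point = sweep(radius * n, 2, center, "+"), normal = n,
         center = center, radius = radius),
    class = "tangent_envelope")
}

#' Distances from probe points to each line of an envelope
#'
#' Perpendicular (unsigned) Euclidean distance from each probe point to
#' each tangent line; used mainly for testing the envelope approximation.
#'
#' @param env a [tangent_envelope()].
#' @param x length-2 point or n-by-2 matrix of probe points.
#' @return n-by-t matrix of distances.
#' @export
envelope_line_distances <- function(env, x) {
  x <- if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 2)
  # |<n_k, x - p_k>|; <n_k, p_k> = <n_k, center> + r
  off <- as.numeric(env$normal %*% env$center) + env$radius
  abs(sweep(x %*% t(env$normal), 2, off))
}

to_matrix3 <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3L)
    x
  } else {
    matrix(as.numeric(x), ncol = 3)
  }
}

check_spd <- function(S, what = "covariance") {
  S <- as.matrix(S)
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8)) ||
      inherits(try(chol(S), silent = TRUE), "try-error")) {
    stop("invalid ", what, ": must be symmetric positive-definite")
  }
  invisible(TRUE)
}
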